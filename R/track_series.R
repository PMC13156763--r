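## TrackSeries: the unit of exchange between tracker, corrector and
## kinematics. A wide per-frame table plus calibration metadata.

#' Construct a track series
#'
#' @param frames `data.frame` with columns `frame` (0-based, strictly
#'   increasing by 1), `cx`, `cy` (centroid, px), `s1x`, `s1y`, ...,
#'   `s<n>x`, `s<n>y` (midline points, caudal to cranial), `headx`, `heady`,
#'   `area` (foreground px^2) and `flag` (`"ok"`, `"no_fish"` or
#'   `"low_confidence"`).
#' @param fps Frames per second (> 0).
#' @param mm_per_px Calibration in mm per px (> 0).
#' @param n_midline Number of midline points n.
#' @param params Optional list of tracker parameters used.
#' @return An object of class `track_series`.
#' @export
track_series <- function(frames, fps, mm_per_px, n_midline, params = list()) {
  stopifnot(fps > 0, mm_per_px > 0, n_midline >= 4)
  need <- c("frame", "cx", "cy", point_cols(n_midline), "headx", "heady",
            "area", "flag")
  miss <- setdiff(need, names(frames))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(frames) > 1 && any(diff(frames$frame) != 1))
    stop("frame indices must increase by 1")
  structure(list(frames = frames[need], fps = fps, mm_per_px = mm_per_px,
                 n_midline = n_midline, params = params),
            class = "track_series")
}

point_cols <- function(n) {
  as.vector(t(outer(paste0("s", 1:n), c("x", "y"), paste0)))
}

## all point columns incl. centroid and head, in interpolation order
all_point_cols <- function(n) c("cx", "cy", point_cols(n), "headx", "heady")

## (n+1) x 2 matrix of S1..Sn + head for one row of the frames table
midline_points_of_row <- function(row, n) {
  cols <- c(point_cols(n), "headx", "heady")
  matrix(as.numeric(row[1, cols]), ncol = 2, byrow = TRUE)
}

set_midline_points_of_row <- function(row, P, n) {
  cols <- c(point_cols(n), "headx", "heady")
  row[1, cols] <- as.vector(t(P))
  row
}

#' @export
print.track_series <- function(x, ...) {
  cat(sprintf("track_series: %d frames @ %g fps, %g mm/px, n = %d midline points\n",
              nrow(x$frames), x$fps, x$mm_per_px, x$n_midline))
  flags <- table(x$frames$flag)
  cat("  flags:", paste(names(flags), as.integer(flags), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a track series as CSV
#'
#' The CSV mirrors the `frames` table; calibration is stored in `# key: value`
#' header comments (frame indices 0-based, pixel units, image coordinates
#' x-right / y-down).
#'
#' @param track A [track_series()].
#' @param path Output path.
#' @return `write_track_csv` returns `path` invisibly; `read_track_csv`
#'   returns a [track_series()].
#' @export
write_track_csv <- function(track, path) {
  hdr <- c(sprintf("# fps: %.10g", track$fps),
           sprintf("# mm_per_px: %.10g", track$mm_per_px),
           sprintf("# n_midline: %d", track$n_midline),
           "# coordinates: pixels, x-right, y-down, origin top-left; frame index 0-based")
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(track$frames, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_num <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, ": *"), "", ln[1]))
  }
  df <- as.data.frame(data.table::fread(path, skip = length(hdr)))
  track_series(df, fps = get_num("fps"), mm_per_px = get_num("mm_per_px"),
               n_midline = as.integer(get_num("n_midline")))
}
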