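## File I/O: lossless video container (multi-page TIFF), setup
## configuration, annotated output, and the one-call analysis wrapper.

#' Write / read a grayscale video as multi-page TIFF
#'
#' Frames are stored losslessly (LZW) in a standard multi-page TIFF
#' container. Matrices are `[x, y]`, 0-255.
#'
#' @param frames List of matrices.
#' @param path File path (`.tif`).
#' @return `write_video` returns `path` invisibly; `read_video` a list of
#'   matrices.
#' @export
write_video <- function(frames, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for video files")
  tiff::writeTIFF(lapply(frames, function(m) t(m) / 255), path,
                  compression = "LZW")
  invisible(path)
}

#' @rdname write_video
#' @export
read_video <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for video files")
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(t(p) * 255)
  })
}

#' Annotate tracked frames
#'
#' Draws the midline points (tail = bright, toward head = dark), the head
#' and the centroid onto copies of the frames, for visual verification of
#' the tracking. Output frames are gray matrices with the marks burned in.
#'
#' @param frames List of `[x, y]` matrices.
#' @param track A [track_series()].
#' @return List of annotated matrices, same length as `frames`.
#' @export
annotate_frames <- function(frames, track) {
  n <- track$n_midline
  out <- frames
  shades <- round(seq(255, 0, length.out = n + 1))
  for (i in seq_along(frames)) {
    row <- track$frames[i, ]
    if (!row$flag %in% c("ok", "low_confidence")) next
    img <- out[[i]]
    P <- midline_points_of_row(row, n)
    for (j in seq_len(n + 1))
      img <- mark_cross(img, P[j, ], shades[j], 1)
    img <- mark_cross(img, c(row$cx, row$cy), 255, 2)
    out[[i]] <- img
  }
  out
}

mark_cross <- function(img, p, value, r) {
  x <- round(p[1]); y <- round(p[2])
  xs <- max(1, x - r):min(nrow(img), x + r)
  ys <- max(1, y - r):min(ncol(img), y + r)
  img[xs, y] <- value
  img[x, ys] <- value
  img
}

#' Read / write a setup configuration
#'
#' Plain `key = value` text (lines starting with `#` ignored). Recognized
#' keys: `video`, `segment_start`, `segment_end` (s), `crop` (x0,y0,x1,y1),
#' `arena` (x1,y1,x2,y2,... polygon), `arena_width_mm`, `arena_height_mm`,
#' `fps`, `mode`, `size`, `n_midline`. Pixel coordinates are x-right /
#' y-down with origin at the crop's top-left; frame indices 0-based.
#'
#' @param path Config file path.
#' @return A named list; numeric where applicable, `arena` as an m x 2
#'   matrix, `crop` as length-4 vector.
#' @export
read_setup_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    cfg[[key]] <- val
  }
  num_keys <- c("segment_start", "segment_end", "arena_width_mm",
                "arena_height_mm", "fps", "n_midline")
  for (k in intersect(num_keys, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!is.null(cfg$crop))
    cfg$crop <- as.numeric(strsplit(cfg$crop, ",")[[1]])
  if (!is.null(cfg$arena)) {
    a <- as.numeric(strsplit(cfg$arena, ",")[[1]])
    cfg$arena <- matrix(a, ncol = 2, byrow = TRUE)
  }
  cfg
}

#' One-call gait analysis of a corrected track
#'
#' Derives the kinematic series, detects bends, turns and accelerations,
#' assembles steps, and computes the macro summary.
#'
#' @param track A corrected [track_series()].
#' @param thresholds A [gait_thresholds()] list.
#' @param arena Optional arena polygon (px) for thigmotaxis.
#' @param wall_band_mm Wall band width in mm.
#' @return List: `kinematics`, `bends`, `turns`, `accels`, `steps`, `macro`.
#' @export
analyze_track <- function(track, thresholds = gait_thresholds(),
                          arena = NULL, wall_band_mm = 30) {
  kin <- derive_series(track)
  bends <- detect_bends(kin, thresholds)
  turns <- detect_turns(kin, thresholds)
  accels <- detect_accels(kin, thresholds)
  steps <- assemble_steps(bends, turns, accels, kin, thresholds)
  macro <- macro_summary(kin, bends, turns, steps,
                         positions = cbind(track$frames$cx, track$frames$cy),
                         arena = arena, wall_band_mm = wall_band_mm,
                         thresholds = thresholds)
  list(kinematics = kin, bends = bends, turns = turns, accels = accels,
       steps = steps, macro = macro)
}
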