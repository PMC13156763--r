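## Tracking-error detection and correction.
##
## Misplaced midline points show up as implausibly large frame-to-frame
## jumps of the caudal (S1->S2) and/or cranial (S(n-1)->Sn) segment
## orientations. During genuine rapid turns the per-frame changes reach
## magnitudes of about 18 deg (caudal) and 40 deg (cranial); the appearance
## or resolution of a point misplacement produces jumps well beyond 100 deg.
## The detection threshold of 57 deg sits between the two regimes (17 deg
## above the quickest real movement observed at 100 fps).

#' Per-frame caudal and cranial segment orientations of a track
#'
#' @param track A [track_series()].
#' @return data.frame with `frame`, `theta12` (orientation of S1->S2) and
#'   `theta` (orientation of S(n-1)->Sn), radians, image-coordinate
#'   convention (right turns positive).
#' @export
segment_orientations <- function(track) {
  df <- track$frames
  n <- track$n_midline
  th12 <- atan2(df$s2y - df$s1y, df$s2x - df$s1x)
  cn <- paste0("s", n - 1)
  cn2 <- paste0("s", n)
  th <- atan2(df[[paste0(cn2, "y")]] - df[[paste0(cn, "y")]],
              df[[paste0(cn2, "x")]] - df[[paste0(cn, "x")]])
  data.frame(frame = df$frame, theta12 = th12, theta = th)
}

#' Detect midline point misplacements
#'
#' A transition between consecutive frames whose caudal or cranial
#' orientation change exceeds `threshold` marks the appearance of a
#' misplacement; the next such transition within `max_gap` frames marks its
#' resolution, and the frames strictly between the two transitions are
#' flagged. An appearance with no resolution within `max_gap` frames is left
#' unflagged but recorded as a warning run (not corrected, to avoid
#' overcorrection; errors lasting that long are visible to the researcher).
#'
#' @param track A [track_series()].
#' @param threshold Jump threshold in radians (default 57 deg).
#' @param max_gap Maximum correctable run length in frames.
#' @return An object of class `error_flags`: list with `error_frames`
#'   (0-based indices), `runs` (data.frame: start, end, corrected) and
#'   `warnings` (data.frame of uncorrected appearances).
#' @export
detect_misplacements <- function(track, threshold = 57 * pi / 180,
                                 max_gap = 5) {
  so <- segment_orientations(track)
  nf <- nrow(so)
  if (nf < 2) stop("need at least 2 frames")
  d12 <- abs(wrapped_delta(so$theta12[-nf], so$theta12[-1]))
  dth <- abs(wrapped_delta(so$theta[-nf], so$theta[-1]))
  jump <- (d12 > threshold | dth > threshold)
  jump[is.na(jump)] <- FALSE
  frames <- so$frame
  err <- integer(0)
  runs <- list()
  warns <- list()
  i <- 1
  while (i <= length(jump)) {
    if (jump[i]) {
      ## appearance at transition i (between frames i-1 and i, 1-based rows)
      res <- NA
      for (j in (i + 1):min(i + max_gap, length(jump))) {
        if (j > length(jump)) break
        if (jump[j]) { res <- j; break }
      }
      if (!is.na(res)) {
        flagged <- frames[(i + 1):res]     # strictly between the transitions
        err <- c(err, flagged)
        runs[[length(runs) + 1]] <-
          data.frame(start = flagged[1], end = flagged[length(flagged)],
                     corrected = NA)
        i <- res + 1
      } else {
        warns[[length(warns) + 1]] <-
          data.frame(transition_frame = frames[i],
                     delta12 = d12[i], delta = dth[i])
        i <- i + 1
      }
    } else i <- i + 1
  }
  structure(list(error_frames = err,
                 runs = if (length(runs)) do.call(rbind, runs)
                        else data.frame(start = integer(0), end = integer(0),
                                        corrected = logical(0)),
                 warnings = if (length(warns)) do.call(rbind, warns)
                            else data.frame(transition_frame = integer(0),
                                            delta12 = numeric(0),
                                            delta = numeric(0)),
                 threshold = threshold, max_gap = max_gap),
            class = "error_flags")
}

#' Replace flagged frames by temporal interpolation
#'
#' Every point (centroid, S1..Sn, head) of a flagged frame is replaced by
#' linear interpolation in time between the last clean frame before and the
#' first clean frame after its run. Runs touching the series boundary hold
#' the nearest clean frame. Unflagged frames are returned unchanged.
#'
#' @param track A [track_series()].
#' @param flags An `error_flags` object from [detect_misplacements()].
#' @return A corrected [track_series()].
#' @export
interpolate_midlines <- function(track, flags) {
  if (nrow(flags$runs) == 0) return(track)
  df <- track$frames
  cols <- all_point_cols(track$n_midline)
  for (r in seq_len(nrow(flags$runs))) {
    i0 <- match(flags$runs$start[r], df$frame)
    i1 <- match(flags$runs$end[r], df$frame)
    lo <- i0 - 1
    hi <- i1 + 1
    if (lo < 1 && hi > nrow(df)) next
    for (i in i0:i1) {
      if (lo < 1) {
        df[i, cols] <- df[hi, cols]
      } else if (hi > nrow(df)) {
        df[i, cols] <- df[lo, cols]
      } else {
        w <- (i - lo) / (hi - lo)
        df[i, cols] <- (1 - w) * df[lo, cols] + w * df[hi, cols]
      }
    }
  }
  out <- track
  out$frames <- df
  out
}

#' Detect and correct in one call
#'
#' @inheritParams detect_misplacements
#' @return List: `track` (corrected), `flags`, and `accuracy` (the
#'   [accuracy_index()] of the input track).
#' @export
correct_track <- function(track, threshold = 57 * pi / 180, max_gap = 5) {
  flags <- detect_misplacements(track, threshold, max_gap)
  corrected <- interpolate_midlines(track, flags)
  list(track = corrected, flags = flags,
       accuracy = accuracy_index(length(flags$error_frames),
                                 nrow(track$frames)))
}

#' Tracking accuracy index
#'
#' Fraction of frames tracked without a detected point misplacement:
#' `(total - errors) / total`. (Stated in words elsewhere as "error frames
#' divided by total frames", which is inconsistent with reported
#' near-perfect values of ~1; the complement form reproduces them, e.g.
#' 456.2 mean error frames in 6000 give 0.9240.)
#'
#' @param error_frame_count Number of error frames (may be a fractional
#'   mean across videos).
#' @param total_frames Total frames (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_index <- function(error_frame_count, total_frames) {
  if (total_frames <= 0) stop("total_frames must be > 0")
  if (error_frame_count < 0 || error_frame_count > total_frames)
    stop("error_frame_count must be in [0, total_frames]")
  (total_frames - error_frame_count) / total_frames
}
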