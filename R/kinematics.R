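## Per-frame kinematics: speed v, unwrapped orientation theta, signed bend
## angle alpha, bend position k.

#' Derive per-frame kinematic quantities from a corrected track
#'
#' * `v` — centroid speed, `|dC| * fps * mm_per_px` (mm/s); `v_smooth` is a
#'   centered 5-frame moving average used for episode detection (the raw
#'   series is kept for maximum speed).
#' * `theta` — unwrapped orientation of the cranial segment S(n-1) -> Sn
#'   (rad; a positive change is a rightward turn).
#' * `alpha` — signed bend angle: caudal tangent (S1 -> S2) orientation
#'   minus cranial tangent orientation, wrapped (rad; positive = left bend).
#' * `k` — bend position from [bend_position()] (fraction of body length
#'   from the tail; NA when the midline is straight).
#'
#' @param track A corrected, calibrated [track_series()].
#' @param k_tolerance Local-tangent deviation (rad) that counts as flexion
#'   for the per-frame bend position.
#' @return A `kinematic_series`: data.frame (frame, t, v, v_smooth, theta,
#'   alpha, k, ok) with attributes `fps` and `mm_per_px`. Rows from frames
#'   not flagged `ok` have `ok = FALSE` and NA kinematics.
#' @export
derive_series <- function(track, k_tolerance = 10 * pi / 180) {
  df <- track$frames
  n <- track$n_midline
  fps <- track$fps
  nf <- nrow(df)
  ok <- df$flag %in% c("ok", "low_confidence") & !is.na(df$cx)
  dx <- c(NA, diff(df$cx))
  dy <- c(NA, diff(df$cy))
  v <- sqrt(dx^2 + dy^2) * fps * track$mm_per_px
  if (nf >= 2) v[1] <- v[2]
  so <- segment_orientations(track)
  theta <- unwrap_angles(so$theta)
  alpha <- wrapped_delta(so$theta, so$theta12)
  k <- rep(NA_real_, nf)
  for (i in which(ok)) {
    P <- midline_points_of_row(df[i, ], n)
    k[i] <- bend_position(P, tolerance = k_tolerance)
  }
  v[!ok] <- NA; theta[!ok] <- NA; alpha[!ok] <- NA
  out <- data.frame(frame = df$frame, t = df$frame / fps, v = v,
                    v_smooth = moving_average(v, 5), theta = theta,
                    alpha = alpha, k = k, ok = ok)
  structure(out, fps = fps, mm_per_px = track$mm_per_px,
            class = c("kinematic_series", "data.frame"))
}

moving_average <- function(x, w) {
  if (w <= 1 || length(x) < w) return(x)
  half <- (w - 1) %/% 2
  xs <- x
  xs[is.na(xs)] <- 0
  wts <- !is.na(x)
  num <- stats::filter(xs, rep(1, w), sides = 2)
  den <- stats::filter(as.numeric(wts), rep(1, w), sides = 2)
  out <- as.numeric(num / pmax(den, 1))
  ## shrink the window at the edges
  for (i in seq_len(half)) {
    out[i] <- mean(x[1:(i + half)], na.rm = TRUE)
    out[length(x) - i + 1] <- mean(x[(length(x) - i + 1 - half):length(x)],
                                   na.rm = TRUE)
  }
  out[is.na(x)] <- NA
  out
}

#' Bend position along a midline
#'
#' Walking from the head toward the tail, the first midline segment whose
#' tangent deviates from the cranial axis (the most cranial segment) by more
#' than `tolerance` marks where the distal body begins to be laterally
#' flexed. The returned value is the arc length from the tail point to that
#' flexion point divided by the whole midline arc length (0 = tail,
#' 1 = head). A midline that never deviates returns NA.
#'
#' With n+1 equally spaced landmarks (S1..Sn plus head), flexion beginning
#' at the i-th point from the tail gives k = (i - 1) / n.
#'
#' @param points (m x 2) ordered midline landmarks, tail first, head last
#'   (m >= 3).
#' @param tolerance Angular tolerance in rad.
#' @return k in `[0, 1]` or NA.
#' @export
bend_position <- function(points, tolerance = 10 * pi / 180) {
  m <- nrow(points)
  if (m < 3) stop("need at least 3 midline points")
  seg <- diff(points)
  ang <- atan2(seg[, 2], seg[, 1])
  axis <- ang[m - 1]                        # most cranial segment
  dev <- abs(wrapped_delta(axis, ang))
  bent <- which(dev[-(m - 1)] > tolerance)  # candidate segments below axis
  if (length(bent) == 0) return(NA_real_)
  j <- max(bent)                            # first deviating segment from head
  arc <- c(0, cumsum(sqrt(rowSums(seg^2))))
  arc[j + 1] / arc[m]
}
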