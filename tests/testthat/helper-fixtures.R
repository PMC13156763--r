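## Shared fixtures: small geometric masks and hand-built track series.

## logical mask from a predicate over 1-based pixel coordinates
mask_from <- function(w, h, pred) {
  xs <- matrix(rep(1:w, h), w, h)
  ys <- matrix(rep(1:h, each = w), w, h)
  pred(xs, ys)
}

## a horizontal capsule (stadium): axis y = cy, from x0 to x1, radius r
capsule_mask <- function(w, h, x0, x1, cy, r) {
  mask_from(w, h, function(x, y) {
    ax <- pmin(pmax(x, x0), x1)
    (x - ax)^2 + (y - cy)^2 <= r^2
  })
}

## build a track_series directly from per-frame midline landmark matrices
## pts: list of (n+1) x 2 matrices (S1..Sn, head); centroid = midline mean
track_from_points <- function(pts, fps = 100, mm_per_px = 0.25) {
  n <- nrow(pts[[1]]) - 1
  rows <- lapply(seq_along(pts), function(i) {
    P <- pts[[i]]
    df <- data.frame(frame = i - 1L, cx = mean(P[, 1]), cy = mean(P[, 2]))
    m <- as.data.frame(as.list(stats::setNames(
      as.vector(t(P)), c(fishgait:::point_cols(n), "headx", "heady"))))
    cbind(df, m, data.frame(area = 1000, flag = "ok"))
  })
  track_series(do.call(rbind, rows), fps = fps, mm_per_px = mm_per_px,
               n_midline = n)
}

## straight-fish landmark matrix: n+1 points from tail to head along
## direction `heading` (image-coordinate angle convention), head at `head_pos`
straight_points <- function(n = 10, head_pos = c(200, 180), heading = 0,
                            length_px = 120) {
  u <- c(cos(heading), sin(heading))
  fr <- seq(1, 0, length.out = n + 1)   # head..tail fractions
  P <- t(vapply(rev(fr), function(f) head_pos - u * f * length_px,
                c(0, 0)))
  P
}

## naive Kapur objective for the brute-force oracle: direct two-class
## Shannon entropy sum, written independently of the implementation
kapur_bruteforce <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf
  bestT <- NA
  for (T in 0:254) {
    lo <- p[1:(T + 1)]
    hi <- p[(T + 2):256]
    if (sum(lo) == 0 || sum(hi) == 0) next
    H <- 0
    for (q in lo[lo > 0] / sum(lo)) H <- H - q * log(q)
    for (q in hi[hi > 0] / sum(hi)) H <- H - q * log(q)
    if (H > best) { best <- H; bestT <- T }
  }
  bestT
}
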