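## Posture tracker: frame -> centroid + midline points + head.
##
## Pipeline per frame: Gaussian blur; maximum-entropy binarization (the fish
## is the dark class on a light, backlit background; for adults no background
## subtraction is performed, which is what keeps the translucent pectoral
## fins out of the mask); largest connected component; ordered outer contour;
## tail = sharpest contour point (smallest foreground count in a square
## window); head = sharpest point on the proximal half; midline points =
## midpoints of contour pairs taken at equal arc fractions from the tail on
## the two contour halves.

#' Tracker parameters
#'
#' @param mode `"adult"`, `"juvenile"` or `"larva"`. Adults are binarized
#'   directly (no background subtraction); larvae are tracked on the
#'   background-subtracted difference image; juveniles use both channels,
#'   with a refined caudal point from the subtraction channel.
#' @param n_midline Number of midline points; defaults by size class:
#'   10 (large adult), 7 (small adult), 6 (juvenile), 5 (larva). `size`
#'   selects between the two adult defaults.
#' @param size For adults, `"large"` or `"small"`.
#' @param blur_radius Gaussian blur kernel radius in px (sigma = radius / 2).
#' @param tail_window Odd window side in px for the sharpest-point statistic,
#'   or `NULL` for the scale-adaptive default
#'   `max(5, round(0.15 * sqrt(foreground area)))`, rounded to odd.
#' @param threshold_override Optional fixed threshold level (0-255) replacing
#'   the per-frame maximum-entropy level.
#' @param min_area Minimum foreground component area (px^2) below which a
#'   frame is flagged `no_fish`.
#' @return An object of class `tracker_params`.
#' @export
tracker_params <- function(mode = c("adult", "juvenile", "larva"),
                           n_midline = NULL, size = c("large", "small"),
                           blur_radius = 2, tail_window = NULL,
                           threshold_override = NULL, min_area = 50) {
  mode <- match.arg(mode)
  size <- match.arg(size)
  if (is.null(n_midline))
    n_midline <- switch(mode,
                        adult = if (size == "large") 10L else 7L,
                        juvenile = 6L, larva = 5L)
  if (n_midline < 4) stop("n_midline must be >= 4")
  if (!is.null(tail_window) &&
      (tail_window < 3 || tail_window %% 2 != 1))
    stop("tail_window must be odd and >= 3")
  structure(list(mode = mode, n_midline = as.integer(n_midline),
                 blur_radius = blur_radius, tail_window = tail_window,
                 threshold_override = threshold_override,
                 min_area = min_area),
            class = "tracker_params")
}

#' Median background image from sampled frames
#'
#' @param frames List of equally sized `[x, y]` gray matrices (>= 3).
#' @return Per-pixel median image.
#' @export
estimate_background <- function(frames) {
  if (length(frames) < 3) stop("need at least 3 sampled frames")
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("inconsistent frame sizes")
  arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  apply(arr, c(1, 2), median)
}

## blur an 8-bit [x,y] matrix; sigma = radius/2 (kernel radius convention)
blur_frame <- function(img, blur_radius) {
  if (blur_radius <= 0) return(img)
  b <- EBImage::gblur(img / 255, sigma = blur_radius / 2) * 255
  pmin(pmax(round(b), 0), 255)
}

#' Binarize one frame
#'
#' Adult: blur, then threshold the frame directly; the fish is the
#' at-or-below-threshold (dark) class. Larva: subtract the background, then
#' blur and threshold the (inverted) difference. Juvenile: both channels are
#' returned.
#'
#' @param img `[x, y]` gray matrix, 0-255.
#' @param params A [tracker_params()].
#' @param background Background image (required for larva/juvenile).
#' @return A list with logical masks: `mask` (primary channel) and, for
#'   juveniles, `mask_sub` (background-subtraction channel); plus the
#'   threshold level(s) used. If no foreground survives, `no_fish = TRUE`.
#' @export
binarize_frame <- function(img, params, background = NULL) {
  direct_mask <- function(im) {
    b <- blur_frame(im, params$blur_radius)
    lev <- params$threshold_override
    if (is.null(lev)) {
      counts <- tabulate(c(b) + 1, nbins = 256)
      if (sum(counts > 0) < 2) return(NULL)
      lev <- max_entropy_threshold(counts)
    }
    list(mask = b <= lev, level = lev)
  }
  sub_mask <- function(im) {
    if (is.null(background)) stop("background image required for this mode")
    d <- pmin(pmax(round(background - im), 0), 255)   # fish darker: positive
    b <- blur_frame(d, params$blur_radius)
    counts <- tabulate(c(b) + 1, nbins = 256)
    if (sum(counts > 0) < 2) return(NULL)
    lev <- max_entropy_threshold(counts)
    list(mask = b > lev, level = lev)
  }
  out <- switch(params$mode,
    adult = { m <- direct_mask(img); list(mask = m$mask, level = m$level) },
    larva = { m <- sub_mask(img); list(mask = m$mask, level = m$level) },
    juvenile = {
      m1 <- direct_mask(img); m2 <- sub_mask(img)
      list(mask = m1$mask, level = m1$level,
           mask_sub = m2$mask, level_sub = m2$level)
    })
  if (is.null(out$mask) || !any(out$mask)) out$no_fish <- TRUE
  out
}

#' Centroid of a foreground mask
#'
#' Arithmetic mean of the foreground pixel coordinates (center of mass of
#' the silhouette).
#'
#' @param mask Logical `[x, y]` matrix.
#' @return `(x, y)` in px (1-based pixel centers).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  c(mean(idx[, 1]), mean(idx[, 2]))
}

## Largest connected component and its ordered outer contour.
## Returns list(mask, contour (np x 2, 1-based), area) or NULL if empty.
largest_component_contour <- function(mask) {
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  comp <- lab == big
  oc <- EBImage::ocontour(EBImage::Image(comp * 1))[[1]]
  list(mask = comp, contour = oc + 1, area = sizes[big])
}

## Integral-image window sums of mask at the given centers (vectorized).
window_counts <- function(mask, centers, half) {
  w <- nrow(mask); h <- ncol(mask)
  ## integral image via whole-vector cumsums (fast column/row cumsum)
  col_cumsum <- function(m) {
    cs <- matrix(cumsum(m), nrow(m), ncol(m))
    prev <- c(0, cs[nrow(m), -ncol(m)])
    cs - matrix(prev, nrow(m), ncol(m), byrow = TRUE)
  }
  S <- matrix(0, w + 1, h + 1)
  S[-1, -1] <- t(col_cumsum(t(col_cumsum(mask * 1))))
  x1 <- pmax(centers[, 1] - half, 1); x2 <- pmin(centers[, 1] + half, w)
  y1 <- pmax(centers[, 2] - half, 1); y2 <- pmin(centers[, 2] + half, h)
  S[cbind(x2 + 1, y2 + 1)] - S[cbind(x1, y2 + 1)] -
    S[cbind(x2 + 1, y1)] + S[cbind(x1, y1)]
}

## Sub-pixel tail estimate: mean of the contour pixels whose window count
## is within 1 of the minimum, restricted to the contiguous neighborhood
## of the sharpest pixel (within one window side along the contour).
subpixel_tail <- function(contour, mask, i_tail, tail_window) {
  np <- nrow(contour)
  half <- (tail_window - 1) / 2
  idx_dist <- pmin(abs(seq_len(np) - i_tail), np - abs(seq_len(np) - i_tail))
  nb <- which(idx_dist <= tail_window)
  ws <- window_counts(mask, contour[nb, , drop = FALSE], half)
  near <- nb[ws <= min(ws) + 1]
  colMeans(contour[near, , drop = FALSE])
}

default_tail_window <- function(area) {
  tw <- max(5, round(0.15 * sqrt(area)))
  if (tw %% 2 == 0) tw <- tw + 1
  as.integer(tw)
}

#' Locate the tail point S1 on a contour
#'
#' The tail is the sharpest point of the outline: the contour pixel whose
#' surrounding `tail_window` x `tail_window` square contains the fewest
#' foreground pixels. Exact ties resolve to the smallest contour index and
#' set the `low_confidence` attribute.
#'
#' @param contour np x 2 matrix of ordered, closed contour pixels (1-based).
#' @param mask Logical foreground mask the contour belongs to.
#' @param tail_window Odd window side in px.
#' @return Index into `contour` rows, with attributes `point` (x, y) and
#'   `low_confidence`.
#' @export
locate_tail <- function(contour, mask, tail_window) {
  if (nrow(contour) < 8) stop("degenerate contour (< 8 pixels)")
  half <- (tail_window - 1) / 2
  ws <- window_counts(mask, contour, half)
  i <- which.min(ws)
  ## adjacent-pixel ties are normal discretization; only ties at a distinct
  ## contour location (e.g. a circle, where every point ties) are ambiguous
  ties <- which(ws == ws[i])
  np <- nrow(contour)
  idx_dist <- pmin(abs(ties - i), np - abs(ties - i))
  structure(i, point = contour[i, ],
            low_confidence = any(idx_dist > 2 * tail_window))
}

#' Locate the head point on a contour
#'
#' Minimizes the same window statistic as [locate_tail()], restricted to the
#' proximal half of the outline: contour pixels whose arc distance from S1
#' exceeds a quarter of the perimeter in both directions.
#'
#' @param contour,mask,tail_window As in [locate_tail()].
#' @param i_tail Contour row index of S1.
#' @return Index into `contour` rows, with attributes as in [locate_tail()].
#' @export
locate_head <- function(contour, mask, i_tail, tail_window, tie_slack = 1) {
  np <- nrow(contour)
  if (np < 8) stop("degenerate contour (< 8 pixels)")
  seg <- sqrt(rowSums((contour - contour[c(2:np, 1), , drop = FALSE])^2))
  per <- sum(seg)
  ord <- c(i_tail:np, if (i_tail > 1) 1:(i_tail - 1))
  d <- c(0, cumsum(seg[ord]))[1:np]
  dfrom <- numeric(np)
  dfrom[ord] <- d
  arcd <- pmin(dfrom, per - dfrom)
  cand <- which(arcd > per / 4)
  if (length(cand) == 0) stop("proximal half of the contour is empty")
  half <- (tail_window - 1) / 2
  ws <- window_counts(mask, contour[cand, , drop = FALSE], half)
  ## The square-window statistic is rotation dependent: on a rounded snout
  ## its minimum can sit on the cap shoulders rather than on the apex. Use
  ## the near-minimal stretch for a coarse location, then refine to the
  ## boundary point of maximal cranial extent (projection onto the axis
  ## from the mask centroid through the coarse point) in its neighborhood.
  near <- cand[ws <= min(ws) + tie_slack]
  ctr <- colMeans(contour[near, , drop = FALSE])
  i0 <- near[which.min((contour[near, 1] - ctr[1])^2 +
                         (contour[near, 2] - ctr[2])^2)]
  cen <- mask_centroid(mask)
  u <- contour[i0, ] - cen
  u <- u / sqrt(sum(u^2))
  idx_dist <- pmin(abs(seq_len(np) - i0), np - abs(seq_len(np) - i0))
  nb <- which(idx_dist <= 2 * tail_window)
  proj <- (contour[nb, 1] - cen[1]) * u[1] + (contour[nb, 2] - cen[2]) * u[2]
  ## the extreme front can be several pixels wide; take the centre of the
  ## near-maximal face rather than an arbitrary edge of it
  front <- nb[proj >= max(proj) - 0.75]
  fc <- colMeans(contour[front, , drop = FALSE])
  i <- front[which.min((contour[front, 1] - fc[1])^2 +
                         (contour[front, 2] - fc[2])^2)]
  structure(i, point = contour[i, ],
            low_confidence = FALSE)
}

## linear interpolation along a polyline at arc-length fractions
sample_polyline <- function(pts, fracs) {
  d <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  tot <- d[length(d)]
  out <- matrix(NA_real_, length(fracs), 2)
  for (i in seq_along(fracs)) {
    target <- fracs[i] * tot
    j <- findInterval(target, d, all.inside = TRUE)
    wgt <- (target - d[j]) / max(d[j + 1] - d[j], 1e-9)
    out[i, ] <- pts[j, ] * (1 - wgt) + pts[j + 1, ] * wgt
  }
  out
}

#' Midline points from a split contour
#'
#' The contour is cut at S1 and the head into two arcs; each arc is sampled
#' at arc-length fractions i/n (i = 1..n-1) from the tail, and corresponding
#' samples are averaged into the midline points S2..Sn. Together with S1 and
#' the head this yields n+1 landmarks at equal arc fractions of the body.
#'
#' @param contour np x 2 ordered closed contour (1-based px).
#' @param i_tail,i_head Contour row indices of S1 and the head.
#' @param n_midline Number of midline points n.
#' @return (n+1) x 2 matrix: S1, S2..Sn, head.
#' @export
midline_points <- function(contour, i_tail, i_head, n_midline) {
  np <- nrow(contour)
  if (i_tail == i_head) stop("tail and head coincide")
  arc1 <- if (i_tail <= i_head) i_tail:i_head else c(i_tail:np, 1:i_head)
  arc2 <- if (i_head <= i_tail) i_head:i_tail else c(i_head:np, 1:i_tail)
  arc2 <- rev(arc2)
  if (length(arc1) < 2 || length(arc2) < 2) stop("contour arc of zero length")
  fr <- seq_len(n_midline - 1) / n_midline
  A1 <- sample_polyline(contour[arc1, , drop = FALSE], fr)
  A2 <- sample_polyline(contour[arc2, , drop = FALSE], fr)
  rbind(contour[i_tail, ], (A1 + A2) / 2, contour[i_head, ])
}

#' Refine the caudal point for juveniles
#'
#' In small fish the directly binarized tail is eroded, so a more distal
#' caudal point S0 is taken from the background-subtraction channel, whose
#' contour retains the lighter tail. Only contour points distal to S1
#' (projecting beyond S1 on the head-to-tail axis) are candidates, which is
#' what keeps pectoral fins from being selected.
#'
#' @param mask_sub Logical mask from the subtraction channel.
#' @param s1 Caudal point from the direct channel, `(x, y)`.
#' @param head Head point, `(x, y)`.
#' @param tail_window Odd window side in px.
#' @return `(x, y)` of S0, with attribute `refined` (FALSE if no distal
#'   candidate existed and S1 is returned unchanged).
#' @export
refine_tail_juvenile <- function(mask_sub, s1, head, tail_window) {
  lc <- largest_component_contour(mask_sub)
  if (is.null(lc)) return(structure(s1, refined = FALSE))
  axis <- s1 - head
  axis <- axis / sqrt(sum(axis^2))
  proj <- (lc$contour[, 1] - s1[1]) * axis[1] +
          (lc$contour[, 2] - s1[2]) * axis[2]
  cand <- which(proj > 0)
  if (length(cand) == 0) return(structure(s1, refined = FALSE))
  half <- (tail_window - 1) / 2
  ws <- window_counts(lc$mask, lc$contour[cand, , drop = FALSE], half)
  structure(lc$contour[cand[which.min(ws)], ], refined = TRUE)
}

## Track a single frame; returns a one-row data.frame in track_series layout.
track_frame <- function(img, params, frame_index, background = NULL) {
  n <- params$n_midline
  empty <- function(flag) {
    row <- as.data.frame(as.list(setNames(
      rep(NA_real_, 2 * n + 5),
      c("cx", "cy", point_cols(n), "headx", "heady", "area"))))
    cbind(data.frame(frame = frame_index), row, data.frame(flag = flag))
  }
  bin <- binarize_frame(img, params, background)
  if (isTRUE(bin$no_fish)) return(empty("no_fish"))
  lc <- largest_component_contour(bin$mask)
  if (is.null(lc) || lc$area < params$min_area ||
      lc$area > 0.25 * length(img) || nrow(lc$contour) < 8)
    return(empty("no_fish"))
  tw <- if (is.null(params$tail_window)) default_tail_window(lc$area)
        else params$tail_window
  i_tail <- locate_tail(lc$contour, lc$mask, tw)
  i_head <- locate_head(lc$contour, lc$mask, i_tail, tw)
  P <- midline_points(lc$contour, i_tail, i_head, n)
  ## sub-pixel caudal point: centre of the near-minimal stretch of the
  ## window statistic around the tail pixel (the integer contour pixel
  ## otherwise injects ~1 px jitter straight into the bend angle)
  P[1, ] <- subpixel_tail(lc$contour, lc$mask, i_tail, tw)
  low_conf <- attr(i_tail, "low_confidence") || attr(i_head, "low_confidence")
  if (params$mode == "juvenile" && !is.null(bin$mask_sub) && any(bin$mask_sub)) {
    s0 <- refine_tail_juvenile(bin$mask_sub, P[1, ], P[n + 1, ], tw)
    if (!attr(s0, "refined")) low_conf <- TRUE
    P[1, ] <- s0
  }
  cen <- mask_centroid(lc$mask)
  row <- data.frame(frame = frame_index, cx = cen[1], cy = cen[2])
  pts <- as.data.frame(as.list(setNames(as.vector(t(P)),
                                        c(point_cols(n), "headx", "heady"))))
  cbind(row, pts, data.frame(area = lc$area,
                             flag = if (low_conf) "low_confidence" else "ok"))
}

#' Track a video (list of frames) into a track series
#'
#' Applies the per-frame pipeline to every frame. Frames that fail a stage
#' are flagged (`no_fish`), never dropped: the output always has one row per
#' input frame.
#'
#' @param frames List of `[x, y]` gray matrices (0-255), or the `frames`
#'   element of [render_swim_video()].
#' @param params A [tracker_params()].
#' @param fps Frames per second.
#' @param mm_per_px Calibration, mm per px (see [calibrate_mm_per_px()]).
#' @param background Optional background image for larva/juvenile modes;
#'   estimated from up to 15 evenly sampled frames when needed and absent.
#' @return A [track_series()].
#' @export
track_video <- function(frames, params = tracker_params(), fps, mm_per_px,
                        background = NULL) {
  if (params$mode != "adult" && is.null(background)) {
    take <- unique(round(seq(1, length(frames), length.out = min(15, length(frames)))))
    background <- estimate_background(frames[take])
  }
  rows <- vector("list", length(frames))
  for (i in seq_along(frames))
    rows[[i]] <- track_frame(frames[[i]], params, i - 1L, background)
  track_series(do.call(rbind, rows), fps = fps, mm_per_px = mm_per_px,
               n_midline = params$n_midline,
               params = unclass(params))
}

#' Calibration from arena geometry
#'
#' @param arena_mm Physical arena width in mm.
#' @param arena_px The same extent in px (e.g. from the setup polygon).
#' @return mm per px.
#' @export
calibrate_mm_per_px <- function(arena_mm, arena_px) {
  stopifnot(arena_mm > 0, arena_px > 0)
  arena_mm / arena_px
}
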