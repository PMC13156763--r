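## Synthetic fish fixtures: silhouette renderer, burst-and-coast kinematics
## simulator, and track-level error injection, all with exact ground truth.

#' Synthetic fish shape specification
#'
#' Describes the silhouette that [render_fish_mask()] sweeps along a bent
#' midline: overall length, a half-width profile (blunt near the head,
#' tapering to a point at the tail), and the gray levels of the scene.
#'
#' The arena is backlit: the body is heavily pigmented (dark) while the
#' pectoral fins are translucent and take almost the local background
#' brightness. Fins are therefore rendered at `local background - fin_contrast`
#' gray levels rather than at a fixed dark value; an opaque `fin_gray`
#' override is available to provoke the classic fin-interference tracking
#' failure on purpose. A radial illumination falloff (`vignette`) darkens the
#' arena corners, which is what gives the background histogram the spread a
#' maximum-entropy threshold needs to sit clear of the fin gray levels.
#'
#' @param body_length Body length in px (>= 20).
#' @param body_gray Body gray level (dark), 0-255.
#' @param background_gray Background gray level at the arena centre.
#' @param vignette Illumination falloff amplitude: corners are
#'   `background_gray - vignette`.
#' @param fins Logical; render pectoral fin lobes?
#' @param fin_contrast Fin darkening below the local background (gray levels).
#' @param fin_gray Optional absolute fin gray level overriding the
#'   translucent model (must satisfy `body_gray < fin_gray < background_gray`).
#' @param width_profile Function of normalized arc position `t` in `[0, 1]`
#'   (0 = tail) and `body_length`, returning half-widths in px (> 0 on (0,1)).
#' @return An object of class `fish_shape`.
#' @export
fish_shape <- function(body_length = 120, body_gray = 30, background_gray = 230,
                       vignette = 20, fins = TRUE, fin_contrast = 6,
                       fin_gray = NULL, width_profile = default_width_profile) {
  stopifnot(body_length >= 20, body_gray >= 0, background_gray <= 255,
            vignette >= 0, fin_contrast > 0)
  if (!is.null(fin_gray) &&
      !(body_gray < fin_gray && fin_gray < background_gray))
    stop("fin_gray must lie strictly between body_gray and background_gray")
  if (body_gray >= background_gray - vignette - fin_contrast)
    stop("body must be darker than the darkest background")
  structure(list(body_length = body_length, body_gray = body_gray,
                 background_gray = background_gray, vignette = vignette,
                 fins = fins, fin_contrast = fin_contrast, fin_gray = fin_gray,
                 width_profile = width_profile),
            class = "fish_shape")
}

#' Default half-width profile of the synthetic fish
#'
#' Piecewise profile in units of px: a caudal filament thinning to ~0.6 px
#' over the last 10 % of the body (so the tail is always the sharpest point
#' of the outline), a broad trunk peaking near 62 % of the body, and a
#' superelliptical snout cap.
#'
#' @param t Normalized arc position from the tail, in `[0, 1]`.
#' @param body_length Body length in px.
#' @return Half-widths in px, bounded below by 0.6 px.
#' @export
default_width_profile <- function(t, body_length) {
  wmax <- body_length / 8
  w <- numeric(length(t))
  a <- t <= 0.62
  w[a] <- wmax * (t[a] / 0.62)^0.6
  b <- t > 0.62 & t <= 0.88
  w[b] <- wmax * (1 - 0.5 * ((t[b] - 0.62) / 0.26)^1.2)
  cc <- t > 0.88
  u <- (t[cc] - 0.88) / 0.12
  w[cc] <- 0.5 * wmax * pmax(0, 1 - u^2)^0.8
  ## caudal filament: the last 10 % of the body thins to ~0.6 px so the
  ## tail is always the sharpest point of the outline
  fil <- t < 0.1
  if (any(fil)) {
    wt <- wmax * (0.1 / 0.62)^0.6
    w[fil] <- 0.6 + (wt - 0.6) * (t[fil] / 0.1)^2.5
  }
  pmax(w, 0.6)
}

#' Synthetic fish pose
#'
#' Position is the midline midpoint (50 % arc position); heading is the
#' orientation of the rigid cranial segment in the package angle convention
#' (see [fishgait]). Bending is modeled as a rigid cranial segment plus a
#' uniformly curved distal segment: flexion begins at `bend_onset` body
#' lengths from the tail and the distal tangent rotates by `bend_amplitude`
#' in total (left-positive).
#'
#' @param position Length-2 `(x, y)` in px.
#' @param heading Heading in rad.
#' @param bend_amplitude Signed bend angle in rad, `|amp| < pi/2`;
#'   positive = tail to the fish's left.
#' @param bend_onset Fraction of body length from the tail where flexion
#'   begins, in `(0, 1]`.
#' @return An object of class `fish_pose`.
#' @export
fish_pose <- function(position, heading = 0, bend_amplitude = 0,
                      bend_onset = 0.6) {
  stopifnot(length(position) == 2, is.finite(heading),
            abs(bend_amplitude) < pi / 2,
            bend_onset > 0, bend_onset <= 1)
  structure(list(position = as.numeric(position), heading = heading,
                 bend_amplitude = bend_amplitude, bend_onset = bend_onset),
            class = "fish_pose")
}

## Dense midline polyline for a pose: matrix (x, y, s), s = arc length from
## the tail, row 1 = tail tip, last row = snout (width -> 0 there).
fish_midline <- function(shape, pose, n_samples = NULL) {
  L <- shape$body_length
  if (is.null(n_samples)) n_samples <- max(96, ceiling(2 * L))
  s <- seq(0, L, length.out = n_samples)
  s_bend <- pose$bend_onset * L
  ## image-coordinate tangent angle along the body (tail -> head); a
  ## left-positive bend displaces the tail to the fish's left, so the tail
  ## tangent is heading + bend_amplitude
  ang <- rep(pose$heading, n_samples)
  distal <- s < s_bend
  ang[distal] <- pose$heading +
    pose$bend_amplitude * (s_bend - s[distal]) / s_bend
  ds <- diff(s)
  x <- cumsum(c(0, ds * cos(ang[-1])))
  y <- cumsum(c(0, ds * sin(ang[-1])))
  mid_i <- which.min(abs(s - L / 2))
  x <- x - x[mid_i] + pose$position[1]
  y <- y - y[mid_i] + pose$position[2]
  cbind(x = x, y = y, s = s)
}

## Equally spaced true midline landmarks: S1..Sn at arc fractions
## (i-1)/n from the tail plus the head point at fraction 1, as an
## (n_midline + 1) x 2 matrix.
true_midline_points <- function(midline, n_midline) {
  fr <- (0:n_midline) / n_midline
  s <- midline[, "s"]
  cbind(approx(s, midline[, "x"], xout = fr * max(s))$y,
        approx(s, midline[, "y"], xout = fr * max(s))$y)
}

## background (illumination) image for a canvas
background_image <- function(shape, canvas) {
  w <- canvas[1]; h <- canvas[2]
  gx <- matrix(rep(seq(-1, 1, length.out = w), h), w, h)
  gy <- matrix(rep(seq(-1, 1, length.out = h), each = w), w, h)
  shape$background_gray - shape$vignette * (gx^2 + gy^2) / 2
}


#' Render one synthetic fish frame
#'
#' Sweeps discs of the shape's half-width profile along the bent midline of
#' `pose` over a vignetted background, adds fin lobes (unless disabled) and
#' optional sensor noise, and returns the 8-bit image together with the
#' exact midline used for the sweep.
#'
#' @param shape A [fish_shape()].
#' @param pose A [fish_pose()].
#' @param canvas Length-2 `(width, height)` in px.
#' @param noise_sd Gaussian sensor noise sd in gray levels (0 disables;
#'   drawn from the current RNG state).
#' @return A list with `img` (w x h numeric matrix, 0-255, `[x, y]`
#'   indexing), `midline` (the exact midline polyline swept, columns x/y/s),
#'   `body_mask` (logical), `centroid` (true silhouette centroid, px), and
#'   `fin_mask`.
#' @export
render_fish_mask <- function(shape, pose, canvas, noise_sd = 0) {
  ml <- fish_midline(shape, pose)
  L <- shape$body_length
  t <- ml[, "s"] / L
  r <- shape$width_profile(t, L)
  w <- canvas[1]; h <- canvas[2]
  if (any(ml[, "x"] - max(r) < 1) || any(ml[, "x"] + max(r) > w) ||
      any(ml[, "y"] - max(r) < 1) || any(ml[, "y"] + max(r) > h))
    stop("fish does not fit in the canvas at this pose")
  img <- background_image(shape, canvas)
  fin_mask <- matrix(FALSE, w, h)
  body_mask <- matrix(FALSE, w, h)
  if (shape$fins) {
    i0 <- which.min(abs(t - 0.625))
    j0 <- min(i0 + 1, nrow(ml))
    tang <- c(ml[j0, 1] - ml[i0, 1], ml[j0, 2] - ml[i0, 2])
    tang <- tang / sqrt(sum(tang^2))
    nrm <- c(-tang[2], tang[1])
    a <- L * 0.09; b <- L * 0.055
    for (side in c(-1, 1)) {
      cx <- ml[i0, 1] + side * nrm[1] * (r[i0] + L * 0.05)
      cy <- ml[i0, 2] + side * nrm[2] * (r[i0] + L * 0.05)
      xs <- max(1L, floor(cx - a)):min(w, ceiling(cx + a))
      ys <- max(1L, floor(cy - a)):min(h, ceiling(cy + a))
      dx <- xs - cx
      dy <- ys - cy
      u <- outer(dx * tang[1], dy * tang[2], "+")
      v <- outer(dx * nrm[1], dy * nrm[2], "+")
      inside <- (u / a)^2 + (v / b)^2 <= 1
      sub <- img[xs, ys, drop = FALSE]
      val <- if (is.null(shape$fin_gray)) sub - shape$fin_contrast
             else matrix(shape$fin_gray, length(xs), length(ys))
      sub[inside] <- val[inside]
      img[xs, ys] <- sub
      subm <- fin_mask[xs, ys, drop = FALSE]; subm[inside] <- TRUE
      fin_mask[xs, ys] <- subm
    }
  }
  ## disc sweep, in place (avoid per-disc matrix copies)
  for (i in seq_len(nrow(ml))) {
    cx <- ml[i, 1]; cy <- ml[i, 2]; rad <- r[i]
    xs <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad))
    ys <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad))
    px <- outer((xs - cx)^2, (ys - cy)^2, "+") <= rad^2
    sub <- img[xs, ys, drop = FALSE]; sub[px] <- shape$body_gray
    img[xs, ys] <- sub
    subm <- body_mask[xs, ys, drop = FALSE]; subm[px] <- TRUE
    body_mask[xs, ys] <- subm
  }
  fin_mask <- fin_mask & !body_mask
  if (noise_sd > 0)
    img <- img + matrix(rnorm(w * h, 0, noise_sd), w, h)
  img <- pmin(pmax(round(img), 0), 255)
  idx <- which(body_mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  list(img = img, midline = ml, body_mask = body_mask,
       fin_mask = fin_mask, centroid = centroid)
}

#' Burst-and-coast swim script
#'
#' A deterministic script of discrete steps. Each event is one step: a burst
#' of `n_bends` tail sweeps at `bend_freq` (half-cycle) wave frequency
#' peaking at `peak_bend`, accompanied by a heading change of `turn_angle`
#' and a speed gain of `speed_gain`, followed by a passive coast occupying
#' `coast_frac` of the step duration.
#'
#' @param duration Total duration in s.
#' @param fps Frames per second (> 0).
#' @param events `data.frame` with columns `t_start` (s), `n_bends` (>= 2),
#'   `bend_freq` (Hz, > 0), `peak_bend` (rad, signed, left-positive),
#'   `turn_angle` (rad, positive = right), `speed_gain` (mm/s, > 0),
#'   `coast_frac` (in (0, 1)), `bend_onset` (fraction from tail).
#' @param seed Integer seed recorded with the script (used by consumers for
#'   any stochastic additions such as sensor noise).
#' @param v0 Baseline (coast floor) speed in mm/s.
#' @param theta0 Initial heading in rad.
#' @return An object of class `swim_script`.
#' @export
swim_script <- function(duration, fps, events, seed = 1L, v0 = 3,
                        theta0 = 0) {
  stopifnot(duration > 0, fps > 0)
  need <- c("t_start", "n_bends", "bend_freq", "peak_bend", "turn_angle",
            "speed_gain", "coast_frac", "bend_onset")
  if (nrow(events) > 0) {
    stopifnot(all(need %in% names(events)), all(events$bend_freq > 0),
              all(events$n_bends >= 2), all(events$coast_frac > 0),
              all(events$coast_frac < 1))
    events <- events[order(events$t_start), , drop = FALSE]
    burst <- events$n_bends / (2 * events$bend_freq)
    step_end <- events$t_start + burst / (1 - events$coast_frac)
    if (nrow(events) > 1 &&
        any(step_end[-nrow(events)] > events$t_start[-1] + 1e-9))
      stop("script events overlap in time")
    if (tail(step_end, 1) > duration + 1e-9)
      stop("last event extends past the script duration")
  }
  structure(list(duration = duration, fps = fps, events = events,
                 seed = as.integer(seed), v0 = v0, theta0 = theta0),
            class = "swim_script")
}

#' Draw a random frame-aligned swim script
#'
#' Event timing is quantized to the frame grid (bend half-periods are whole
#' numbers of frames) so that scripted episode boundaries coincide with
#' sampled frames and ground truth is exact. Parameter ranges follow adult
#' zebrafish burst-and-coast swimming: 2-4 tail sweeps per burst at 6-17 Hz
#' half-cycle rate, peak bends 15-40 deg, turns 15-45 deg, speed gains
#' 30-80 mm/s and coast fractions 0.4-0.65.
#'
#' @param seed Integer seed.
#' @param duration Duration in s.
#' @param fps Frames per second.
#' @param n_steps Number of steps (default fills the duration loosely).
#' @param turn_bias Probability that a turn goes right (0.5 = unbiased; 1 or
#'   0 yields fully lateralized scripts for asymmetry tests).
#' @return A [swim_script()].
#' @export
random_swim_script <- function(seed, duration = 10, fps = 100,
                               n_steps = NULL, turn_bias = 0.5) {
  set.seed(seed)
  if (is.null(n_steps)) n_steps <- max(1L, floor(duration / 0.8))
  dt <- 1 / fps
  ev <- vector("list", n_steps)
  t_cur <- 0.3
  for (i in seq_len(n_steps)) {
    m <- sample(3:8, 1)                      # bend half-period in frames
    b <- sample(2:4, 1)
    f <- fps / (2 * m)
    right <- runif(1) < turn_bias
    turn <- (if (right) 1 else -1) * runif(1, 15, 45) * pi / 180
    peak <- -sign(turn) * runif(1, 15, 40) * pi / 180  # bend into the turn
    coast <- runif(1, 0.4, 0.65)
    burst_frames <- b * m
    step_frames <- ceiling(burst_frames / (1 - coast))
    coast_frac <- 1 - burst_frames / step_frames
    ev[[i]] <- data.frame(
      t_start = t_cur, n_bends = b, bend_freq = f, peak_bend = peak,
      turn_angle = turn, speed_gain = runif(1, 30, 80),
      coast_frac = coast_frac, bend_onset = runif(1, 0.5, 0.75))
    gap_frames <- sample(25:60, 1)
    t_cur <- t_cur + (step_frames + gap_frames) * dt
  }
  events <- do.call(rbind, ev)
  events <- events[events$t_start + events$n_bends /
                     (2 * events$bend_freq * (1 - events$coast_frac)) <
                     duration - 0.05, , drop = FALSE]
  swim_script(duration, fps, events, seed = seed)
}

## smoothstep and its max slope factor (3/2)
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate per-frame kinematics for a swim script
#'
#' Generates the four per-frame quantities of burst-and-coast swimming. Per
#' step the bend angle is a train of damped half-cosine sweeps between
#' alternating extrema (the last sweep returns to neutral), the orientation
#' ramps by the scripted turn angle across the burst, and speed rises by the
#' scripted gain across the burst then decays exponentially through the
#' coast. Bend position is the scripted flexion onset during the burst and
#' undefined (NA) elsewhere.
#'
#' @param script A [swim_script()].
#' @param damping Per-sweep amplitude decay of successive bend extrema.
#' @return A list with `series` (data.frame: frame, t, v, theta, alpha, k)
#'   and `truth`, a list of data.frames `bends`, `turns`, `accels`, `steps`
#'   holding the exact episode boundaries (0-based frame indices) and
#'   micro-parameters implied by the script.
#' @export
simulate_kinematics <- function(script, damping = 0.75) {
  fps <- script$fps
  n <- round(script$duration * fps)
  tt <- (0:(n - 1)) / fps
  v <- rep(script$v0, n)
  theta <- rep(script$theta0, n)
  alpha <- numeric(n)
  k <- rep(NA_real_, n)
  ev <- script$events
  bends <- turns <- accels <- steps <- list()
  theta_base <- script$theta0
  if (!is.null(ev) && nrow(ev) > 0) for (e in seq_len(nrow(ev))) {
    b <- ev$n_bends[e]; f <- ev$bend_freq[e]
    d <- 1 / (2 * f)
    t0 <- ev$t_start[e]
    burst <- b * d
    coast <- burst * ev$coast_frac[e] / (1 - ev$coast_frac[e])
    step_end <- t0 + burst + coast
    ## bend extrema sequence: 0, e1, ..., e_{b-1}, 0
    ex <- numeric(b + 1)
    ex[2] <- ev$peak_bend[e]
    if (b > 2) for (j in 3:b) ex[j] <- -ex[j - 1] * damping
    ## half-cosine sweeps
    for (j in seq_len(b)) {
      ts <- t0 + (j - 1) * d
      sel <- tt >= ts - 1e-9 & tt <= ts + d + 1e-9
      u <- (tt[sel] - ts) / d
      alpha[sel] <- ex[j] + (ex[j + 1] - ex[j]) * (1 - cos(pi * u)) / 2
      bends[[length(bends) + 1]] <- data.frame(
        step = e, start_frame = round(ts * fps), end_frame = round((ts + d) * fps),
        delta = ex[j + 1] - ex[j],
        direction = ifelse(ex[j + 1] - ex[j] > 0, "left", "right"),
        angular_velocity = pi * abs(ex[j + 1] - ex[j]) / (2 * d),
        duration = d)
    }
    in_burst <- tt >= t0 - 1e-9 & tt <= t0 + burst + 1e-9
    u <- (tt[in_burst] - t0) / burst
    theta[in_burst] <- theta_base + ev$turn_angle[e] * smoothstep(u)
    theta[tt > t0 + burst] <- theta_base + ev$turn_angle[e]
    theta_base <- theta_base + ev$turn_angle[e]
    v_start <- v[max(1, floor(t0 * fps))]
    v_peak <- v_start + ev$speed_gain[e]
    v[in_burst] <- v_start + ev$speed_gain[e] * smoothstep(u)
    after <- tt > t0 + burst
    tau <- max(coast / 3, 1e-6)
    v[after] <- script$v0 + (v_peak - script$v0) *
      exp(-(tt[after] - t0 - burst) / tau)
    k[tt >= t0 - 1e-9 & tt <= t0 + burst + 1e-9] <- ev$bend_onset[e]
    turns[[length(turns) + 1]] <- data.frame(
      step = e, start_frame = round(t0 * fps), end_frame = round((t0 + burst) * fps),
      angle = ev$turn_angle[e],
      direction = ifelse(ev$turn_angle[e] > 0, "right", "left"),
      angular_velocity = 1.5 * abs(ev$turn_angle[e]) / burst,
      duration = burst)
    accels[[length(accels) + 1]] <- data.frame(
      step = e, start_frame = round(t0 * fps), end_frame = round((t0 + burst) * fps),
      speed_change = ev$speed_gain[e],
      acceleration = 1.5 * ev$speed_gain[e] / burst)
    steps[[length(steps) + 1]] <- data.frame(
      step = e, start_frame = round(t0 * fps),
      burst_end_frame = round((t0 + burst) * fps),
      end_frame = round(step_end * fps),
      n_bends = b,
      speed_change = ev$speed_gain[e],
      acceleration = 1.5 * ev$speed_gain[e] / burst,
      turn_angle = ev$turn_angle[e],
      turn_angular_velocity = 1.5 * abs(ev$turn_angle[e]) / burst,
      turn_duration = burst,
      bend_angle_reached = max(abs(ex)),
      bend_angle_traveled = sum(abs(diff(ex))),
      bend_angular_velocity = max(pi * abs(diff(ex)) / (2 * d)),
      bend_duration_total = burst,
      bend_wave_frequency = b / burst,
      coast_duration = coast,
      step_duration = burst + coast,
      coast_percent = coast / (burst + coast))
  }
  series <- data.frame(frame = 0:(n - 1), t = tt, v = v, theta = theta,
                       alpha = alpha, k = k)
  truth <- list(bends = do.call(rbind, bends), turns = do.call(rbind, turns),
                accels = do.call(rbind, accels), steps = do.call(rbind, steps))
  list(series = series, truth = truth)
}

## Integrate the trajectory of the midline midpoint from speed and heading.
## Returns n x 2 positions in px.
integrate_trajectory <- function(series, start_pos, fps, mm_per_px) {
  n <- nrow(series)
  step_px <- series$v / fps / mm_per_px
  ux <- cos(series$theta)
  uy <- sin(series$theta)
  cbind(start_pos[1] + cumsum(c(0, (step_px * ux)[-n])),
        start_pos[2] + cumsum(c(0, (step_px * uy)[-n])))
}

#' Render a synthetic swimming video with exact ground truth
#'
#' Simulates the script with [simulate_kinematics()], integrates the
#' trajectory of the midline midpoint, and renders every frame with
#' [render_fish_mask()]. Deterministic for a fixed script seed.
#'
#' @param shape A [fish_shape()].
#' @param script A [swim_script()].
#' @param canvas `(width, height)` px.
#' @param start_pos Start position of the midline midpoint, px; default is
#'   the canvas centre.
#' @param mm_per_px Calibration used to convert scripted mm/s speeds into
#'   pixel displacements.
#' @param noise_sd Sensor noise sd (gray levels), seeded from the script.
#' @return A list: `frames` (list of w x h matrices), `truth` with
#'   `frames` (frame, t, v, theta, alpha, k, cx, cy), `points` (array
#'   n_frames x (n+1) x 2 of true midline landmarks for `n_points`),
#'   plus the episode/step tables of [simulate_kinematics()]; and
#'   `manifest` (seed, fps, mm_per_px, canvas, shape parameters).
#' @param n_points Number of midline points n for the `points` ground truth.
#' @export
render_swim_video <- function(shape, script, canvas = c(480, 360),
                              start_pos = NULL, mm_per_px = 0.25,
                              noise_sd = 0, n_points = 10) {
  if (is.null(start_pos)) start_pos <- canvas / 2
  sim <- simulate_kinematics(script)
  series <- sim$series
  pos <- integrate_trajectory(series, start_pos, script$fps, mm_per_px)
  n <- nrow(series)
  set.seed(script$seed)
  frames <- vector("list", n)
  pts <- array(NA_real_, c(n, n_points + 1, 2))
  cxy <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    pose <- fish_pose(pos[i, ], heading = series$theta[i],
                      bend_amplitude = series$alpha[i],
                      bend_onset = if (is.na(series$k[i])) 0.6 else series$k[i])
    fr <- render_fish_mask(shape, pose, canvas, noise_sd = noise_sd)
    frames[[i]] <- fr$img
    pts[i, , ] <- true_midline_points(fr$midline, n_points)
    cxy[i, ] <- fr$centroid
  }
  truth_frames <- cbind(series, cx = cxy[, 1], cy = cxy[, 2])
  list(frames = frames,
       truth = c(list(frames = truth_frames, points = pts), sim$truth),
       manifest = list(seed = script$seed, fps = script$fps,
                       mm_per_px = mm_per_px, canvas = canvas,
                       body_length = shape$body_length,
                       events = script$events))
}

#' Draw a random script whose trajectory stays inside the canvas
#'
#' Builds a script event by event from the same parameter distributions as
#' [random_swim_script()], but like a real fish it avoids the walls: if the
#' trajectory projected through a candidate step would bring the fish
#' within 0.7 body lengths of the canvas edge, the turn direction is
#' flipped toward open water and, failing that, the speed gain is halved;
#' a step that still cannot be placed is skipped. Deterministic for a
#' fixed seed.
#'
#' @inheritParams random_swim_script
#' @param shape A [fish_shape()] (for the safety margin).
#' @param canvas,start_pos,mm_per_px Rendering geometry.
#' @return A [swim_script()].
#' @export
random_contained_script <- function(seed, duration = 10, fps = 100,
                                    shape = fish_shape(),
                                    canvas = c(480, 360), start_pos = NULL,
                                    mm_per_px = 0.25) {
  if (is.null(start_pos)) start_pos <- canvas / 2
  margin <- 0.7 * shape$body_length
  inside <- function(pos)
    all(pos[, 1] > margin) && all(pos[, 1] < canvas[1] - margin) &&
    all(pos[, 2] > margin) && all(pos[, 2] < canvas[2] - margin)
  dt <- 1 / fps
  n_steps <- max(1L, floor(duration / 0.8))
  for (k in 0:19) {
    set.seed((seed + 7919 * k) %% .Machine$integer.max)
    events <- NULL
    t_cur <- 0.3
    for (i in seq_len(n_steps)) {
      m <- sample(3:8, 1)
      b <- sample(2:4, 1)
      f <- fps / (2 * m)
      sgn <- sample(c(-1, 1), 1)
      mag <- runif(1, 15, 45) * pi / 180
      pk <- runif(1, 15, 40) * pi / 180
      gain <- runif(1, 30, 80)
      coast <- runif(1, 0.4, 0.65)
      onset <- runif(1, 0.5, 0.75)
      gap_frames <- sample(25:60, 1)
      burst_frames <- b * m
      step_frames <- ceiling(burst_frames / (1 - coast))
      coast_frac <- 1 - burst_frames / step_frames
      if (t_cur + step_frames * dt >= duration - 0.05) break
      ## state at the step start, for the wall-escape (homing) variant
      sc0 <- swim_script(duration, fps,
                         if (is.null(events))
                           data.frame(t_start = numeric(0),
                                      n_bends = numeric(0),
                                      bend_freq = numeric(0),
                                      peak_bend = numeric(0),
                                      turn_angle = numeric(0),
                                      speed_gain = numeric(0),
                                      coast_frac = numeric(0),
                                      bend_onset = numeric(0))
                         else events, seed = seed)
      sim0 <- simulate_kinematics(sc0)
      pos0 <- integrate_trajectory(sim0$series, start_pos, fps, mm_per_px)
      i0 <- min(nrow(pos0), round(t_cur * fps) + 1)
      to_ctr <- atan2(canvas[2] / 2 - pos0[i0, 2], canvas[1] / 2 - pos0[i0, 1])
      home <- wrapped_delta(sim0$series$theta[i0], to_ctr)
      for (variant in 1:5) {
        s2 <- if (variant %% 2 == 0) -sgn else sgn
        g2 <- if (variant > 2) gain / 2 else gain
        trn <- s2 * mag
        if (variant == 5) {
          ## escape turn toward open water
          trn <- sign(home) * min(max(abs(home), 15 * pi / 180), 2.2)
          s2 <- sign(trn)
        }
        ev <- data.frame(t_start = t_cur, n_bends = b, bend_freq = f,
                         peak_bend = -s2 * pk,   # bend into the turn
                         turn_angle = trn, speed_gain = g2,
                         coast_frac = coast_frac, bend_onset = onset)
        cand <- rbind(events, ev)
        sc <- swim_script(duration, fps, cand, seed = seed)
        sim <- simulate_kinematics(sc)
        pos <- integrate_trajectory(sim$series, start_pos, fps, mm_per_px)
        ## look ahead past this step, its rest gap and one spare second
        upto <- min(nrow(pos),
                    round((t_cur + (step_frames + gap_frames) * dt + 1) * fps))
        if (inside(pos[seq_len(upto), , drop = FALSE])) {
          events <- cand
          t_cur <- t_cur + (step_frames + gap_frames) * dt
          break
        }
        if (variant == 5) t_cur <- t_cur + gap_frames * dt   # skip this step
      }
    }
    if (is.null(events)) next
    sc <- swim_script(duration, fps, events, seed = seed)
    sim <- simulate_kinematics(sc)
    pos <- integrate_trajectory(sim$series, start_pos, fps, mm_per_px)
    if (inside(pos)) return(sc)
  }
  stop("no contained script could be built")
}

#' Ground-truth track series for a swim script
#'
#' Builds the track a perfect tracker would produce, straight from the
#' simulated kinematics and the analytic midline geometry — no rendering,
#' no pixel noise. The centroid channel carries the integrated midline
#' midpoint. Used to validate the error corrector and the gait analysis
#' independently of the image pipeline.
#'
#' @param script A [swim_script()].
#' @param shape A [fish_shape()] (geometry source).
#' @param start_pos Start position in px.
#' @param mm_per_px Calibration.
#' @param n_midline Number of midline points.
#' @return List: `track` (a [track_series()]) and `sim` (the
#'   [simulate_kinematics()] output it was built from).
#' @export
simulate_track_series <- function(script, shape = fish_shape(),
                                  start_pos = c(240, 180), mm_per_px = 0.25,
                                  n_midline = 10) {
  sim <- simulate_kinematics(script)
  series <- sim$series
  pos <- integrate_trajectory(series, start_pos, script$fps, mm_per_px)
  n <- nrow(series)
  cols <- c(point_cols(n_midline), "headx", "heady")
  M <- matrix(NA_real_, n, 2 * (n_midline + 1))
  for (i in seq_len(n)) {
    pose <- fish_pose(pos[i, ], heading = series$theta[i],
                      bend_amplitude = series$alpha[i],
                      bend_onset = if (is.na(series$k[i])) 0.6
                                   else series$k[i])
    P <- true_midline_points(fish_midline(shape, pose), n_midline)
    M[i, ] <- as.vector(t(P))
  }
  df <- data.frame(frame = series$frame, cx = pos[, 1], cy = pos[, 2])
  df <- cbind(df, as.data.frame(M))
  names(df) <- c("frame", "cx", "cy", cols)
  df$area <- round(0.16 * shape$body_length^2)
  df$flag <- "ok"
  list(track = track_series(df, fps = script$fps, mm_per_px = mm_per_px,
                            n_midline = n_midline),
       sim = sim)
}

#' Inject midline point misplacements into a track
#'
#' Corrupts S1 (and, for the pectoral mode, the downstream midline points)
#' in the given frames, emulating the two classic tracking failures: the
#' caudal-fin mode collapses S1 onto the trunk by reflecting it through S2
#' (large caudal-segment orientation jump, cranial segment untouched), and
#' the pectoral-fin mode anchors S1 at a pectoral-fin location and drags the
#' whole midline with it (both segment orientations jump).
#'
#' @param track A [track_series()].
#' @param frames Integer vector of 0-based frame indices to corrupt.
#' @param mode `"tail-fin"` or `"pectoral-fin"`.
#' @return A list: `track` (corrupted copy) and `labels` (the corrupted
#'   frame indices, sorted).
#' @export
inject_point_errors <- function(track, frames,
                                mode = c("pectoral-fin", "tail-fin")) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "track_series"))
  df <- track$frames
  if (nrow(df) == 0) stop("empty track")
  frames <- sort(unique(as.integer(frames)))
  if (length(frames) && !all(frames %in% df$frame))
    stop("frames to corrupt must exist in the track")
  n <- track$n_midline
  for (f in frames) {
    i <- match(f, df$frame)
    P <- midline_points_of_row(df[i, ], n)   # (n+1) x 2, S1..Sn, head
    if (mode == "tail-fin") {
      P[1, ] <- 2 * P[2, ] - P[1, ]
    } else {
      ## Pectoral fin: S1 snaps to a lateral fin point at ~60 % of the
      ## midline and the remaining points read the trunk midline backwards
      ## (the reversal failure of fin-anchored splits): both the caudal and
      ## the cranial segment orientations flip by far more than the
      ## detection threshold.
      arc_at <- function(f) sample_polyline(P, f)
      fr <- 0.6 - 0.45 * (0:(n - 1)) / (n - 1)
      Q <- arc_at(fr)
      seg <- Q[1, ] - Q[2, ]
      seg <- seg / sqrt(sum(seg^2))
      larm <- 0.15 * sum(sqrt(rowSums(diff(P)^2)))
      Q[1, ] <- Q[1, ] + c(-seg[2], seg[1]) * larm
      P[1:n, ] <- Q
    }
    df[i, ] <- set_midline_points_of_row(df[i, ], P, n)
  }
  out <- track
  out$frames <- df
  list(track = out, labels = frames)
}
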