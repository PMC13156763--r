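kin_from_series <- function(v = NULL, theta = NULL, alpha = NULL, fps = 100,
                            k = NULL) {
  n <- max(length(v), length(theta), length(alpha))
  if (is.null(v)) v <- rep(0, n)
  if (is.null(theta)) theta <- rep(0, n)
  if (is.null(alpha)) alpha <- rep(0, n)
  if (is.null(k)) k <- rep(NA_real_, n)
  structure(data.frame(frame = 0:(n - 1), t = (0:(n - 1)) / fps, v = v,
                       v_smooth = fishgait:::moving_average(v, 5),
                       theta = theta, alpha = alpha, k = k, ok = TRUE),
            fps = fps, mm_per_px = 0.25,
            class = c("kinematic_series", "data.frame"))
}

test_that("speed, orientation and bend angle follow their definitions", {
  ## stationary fish
  P <- straight_points()
  tr <- track_from_points(rep(list(P), 20))
  kin <- derive_series(tr)
  expect_true(all(kin$v == 0))
  ## centroid advancing 1 px per frame at 100 fps and 0.1 mm/px -> 10 mm/s
  pts <- lapply(0:19, function(i) straight_points(head_pos = c(200 + i, 180)))
  tr2 <- track_from_points(pts, fps = 100, mm_per_px = 0.1)
  kin2 <- derive_series(tr2)
  expect_equal(kin2$v, rep(10, 20), tolerance = 1e-9)
  ## heading rotating 5 deg/frame through +-180: unwrapped, monotone
  pts3 <- lapply(0:100, function(i)
    straight_points(heading = 2.8 + i * 5 * pi / 180))
  kin3 <- derive_series(track_from_points(pts3))
  expect_true(all(diff(kin3$theta) > 0))
  expect_equal(diff(kin3$theta), rep(5 * pi / 180, 100), tolerance = 1e-9)
})

test_that("bend position follows the arc-ratio rule", {
  ## nine equally spaced points, collinear from the head through the 7th
  ## point from the tail, deflected distal to it -> k = 6/8
  P <- t(vapply(0:8, function(i) c(i * 10, 0), c(0, 0)))
  u <- c(-cos(0.6), sin(0.6))                # bent distal direction
  for (i in 6:1) P[i, ] <- P[7, ] + (7 - i) * 10 * u
  expect_equal(bend_position(P, tolerance = 10 * pi / 180), 6 / 8,
               tolerance = 1e-12)
  ## ten points flexed starting at S2 -> k = 1/9
  Q <- t(vapply(0:9, function(i) c(i * 10, 0), c(0, 0)))
  bendang <- 0.5
  Q[1, ] <- Q[2, ] + 10 * c(-cos(bendang), sin(bendang))
  expect_equal(bend_position(Q, tolerance = 10 * pi / 180), 1 / 9,
               tolerance = 0.02)
  ## perfectly straight -> undefined
  R <- t(vapply(0:9, function(i) c(i * 10, 0), c(0, 0)))
  expect_true(is.na(bend_position(R)))
  expect_error(bend_position(R[1:2, ]), "3 midline points")
})

test_that("a half-sine bend is two sweeps, left then right", {
  a <- c(rep(0, 20), 20 * pi / 180 * sin(pi * (0:20) / 20), rep(0, 30))
  kin <- kin_from_series(alpha = a)
  b <- detect_bends(kin)
  expect_equal(nrow(b), 2)
  expect_identical(b$direction, c("left", "right"))
  expect_equal(b$delta, c(20, -20) * pi / 180, tolerance = 1e-6)
})

test_that("sub-amplitude noise yields no bends", {
  set.seed(1)
  ## white noise whose peak-to-peak amplitude stays below the threshold
  kin <- kin_from_series(alpha = runif(300, -2, 2) * pi / 180)
  expect_equal(nrow(detect_bends(kin)), 0)
})

test_that("scripted bends are recovered within 10 percent", {
  ev <- data.frame(t_start = 0.2, n_bends = 3, bend_freq = 12.5,
                   peak_bend = -30 * pi / 180, turn_angle = 25 * pi / 180,
                   speed_gain = 50, coast_frac = 0.5, bend_onset = 0.6)
  sim <- simulate_kinematics(swim_script(1.5, 100, ev))
  kin <- kin_from_series(v = sim$series$v, theta = sim$series$theta,
                         alpha = sim$series$alpha, k = sim$series$k)
  b <- detect_bends(kin)
  expect_equal(nrow(b), 3)
  expect_equal(b$delta, sim$truth$bends$delta, tolerance = 0.1)
})

test_that("turns are rate-thresholded intervals with net angle", {
  ## theta ramps -30 deg over 0.1 s then stays constant: one left turn
  th <- c(rep(0, 30), seq(0, -30, length.out = 11) * pi / 180,
          rep(-30 * pi / 180, 40))
  kin <- kin_from_series(theta = th)
  tu <- detect_turns(kin)
  expect_equal(nrow(tu), 1)
  expect_identical(tu$direction, "left")
  expect_equal(tu$angle, -30 * pi / 180, tolerance = 1e-6)
  expect_equal(tu$duration, 0.1, tolerance = 0.02)
  ## constant orientation: none
  expect_equal(nrow(detect_turns(kin_from_series(theta = rep(1, 50)))), 0)
})

test_that("accelerations run from trough to peak", {
  v <- c(rep(0, 20), seq(0, 50, length.out = 6),
         50 * exp(-(1:60) / 12))
  kin <- kin_from_series(v = v)
  a <- detect_accels(kin)
  expect_equal(nrow(a), 1)
  expect_equal(a$speed_change, 50, tolerance = 5)     # 5-frame smoothing
  expect_equal(nrow(detect_accels(kin_from_series(v = rep(20, 50)))), 0)
})

test_that("steps group bends with their turn and acceleration", {
  ## one step: left bend + obligatory right return bend, one turn, one
  ## acceleration, then a glide
  ev <- data.frame(t_start = 0.3, n_bends = 2, bend_freq = 10,
                   peak_bend = 25 * pi / 180, turn_angle = -30 * pi / 180,
                   speed_gain = 60, coast_frac = 0.5, bend_onset = 0.6)
  sim <- simulate_kinematics(swim_script(1.2, 100, ev))
  kin <- kin_from_series(v = sim$series$v, theta = sim$series$theta,
                         alpha = sim$series$alpha, k = sim$series$k)
  st <- assemble_steps(detect_bends(kin), detect_turns(kin),
                       detect_accels(kin), kin)
  expect_equal(nrow(st), 1)
  expect_equal(st$n_bends, 2)
  expect_false(is.na(st$turn_angle))
  expect_false(is.na(st$speed_change))
  expect_equal(st$bend_angle_reached, 25 * pi / 180, tolerance = 1e-6)
  ## coast percent is a duration ratio in [0, 1]
  expect_true(st$coast_percent >= 0 && st$coast_percent <= 1)
  expect_lte(st$bend_duration_total, st$step_duration + 1e-9)
})

test_that("bend trains separated by quiescence form separate steps", {
  half <- function(s) s * 20 * pi / 180 * sin(pi * (0:20) / 20)
  a <- c(rep(0, 30), half(1), rep(0, 200), half(-1), rep(0, 30))
  kin <- kin_from_series(alpha = a)
  st <- assemble_steps(detect_bends(kin), detect_turns(kin),
                       detect_accels(kin), kin)
  expect_equal(nrow(st), 2)
})

test_that("mirroring a track negates angles and swaps directions", {
  sc <- random_swim_script(seed = 77, duration = 3, fps = 100)
  tr <- simulate_track_series(sc)$track
  mir <- tr
  ycols <- grep("y$", fishgait:::all_point_cols(10), value = TRUE)
  mir$frames[ycols] <- 720 - mir$frames[ycols]
  k1 <- derive_series(tr)
  k2 <- derive_series(mir)
  expect_equal(k2$v, k1$v, tolerance = 1e-9)
  expect_equal(k2$alpha, -k1$alpha, tolerance = 1e-9)
  expect_equal(diff(k2$theta), -diff(k1$theta), tolerance = 1e-9)
  b1 <- detect_bends(k1); b2 <- detect_bends(k2)
  expect_equal(b2$delta, -b1$delta, tolerance = 1e-9)
  expect_identical(b2$direction,
                   unname(c(left = "right", right = "left")[b1$direction]))
  t1 <- detect_turns(k1); t2 <- detect_turns(k2)
  expect_equal(t2$angle, -t1$angle, tolerance = 1e-9)
  st1 <- assemble_steps(b1, t1, detect_accels(k1), k1)
  st2 <- assemble_steps(b2, t2, detect_accels(k2), k2)
  expect_equal(st2$bend_angle_traveled, st1$bend_angle_traveled,
               tolerance = 1e-9)
  expect_equal(st2$step_length, st1$step_length, tolerance = 1e-9)
})

test_that("macro summary matches closed forms", {
  ## stationary 60 s trace
  P <- straight_points()
  tr <- track_from_points(rep(list(P), 600), fps = 10)
  res <- analyze_track(tr)
  expect_equal(res$macro$freezing, 60, tolerance = 0.1)
  expect_equal(res$macro$distance_traveled, 0)
  expect_equal(res$macro$step_count, 0)
  ## constant-speed circular swim: distance = sT, meandering = s/r
  fps <- 50; Tdur <- 20; r_mm <- 30; s_mm <- 45; mmpx <- 0.25
  omega <- s_mm / r_mm                      # rad/s
  nfr <- fps * Tdur
  pts <- lapply(0:(nfr - 1), function(i) {
    phi <- omega * i / fps
    centre <- c(400, 400)
    pos <- centre + r_mm / mmpx * c(cos(phi), sin(phi))   # clockwise as printed
    heading <- phi + pi / 2                 # tangent: steady rightward turning
    ## a short rigid body keeps the centroid essentially on the circle
    straight_points(head_pos = pos, heading = heading, length_px = 8)
  })
  tr2 <- track_from_points(pts, fps = fps, mm_per_px = mmpx)
  res2 <- analyze_track(tr2)
  expect_equal(res2$macro$distance_traveled, s_mm * Tdur, tolerance = 0.02 * s_mm * Tdur)
  expect_equal(res2$macro$meandering, s_mm / r_mm, tolerance = 0.05)
  expect_equal(res2$macro$freezing, 0)
  ## all turning is one direction (rightward here)
  expect_equal(res2$macro$total_turn_angle_left, 0)
  ## thigmotaxis: centroid path vs a tight arena polygon
  arena <- matrix(c(0, 0, 800, 0, 800, 800, 0, 800), ncol = 2, byrow = TRUE)
  m3 <- macro_summary(res2$kinematics, res2$bends, res2$turns, res2$steps,
                      positions = cbind(tr2$frames$cx, tr2$frames$cy),
                      arena = arena, wall_band_mm = 30)
  expect_gte(m3$thigmotaxis_duration, 0)
  expect_lte(m3$thigmotaxis_duration, Tdur)
})

test_that("step lengths never exceed the distance traveled", {
  sc <- random_swim_script(seed = 55, duration = 5, fps = 100)
  tr <- simulate_track_series(sc)$track
  res <- analyze_track(tr)
  expect_lte(sum(res$steps$step_length), res$macro$distance_traveled + 1e-6)
  expect_true(all(res$steps$coast_percent >= 0 & res$steps$coast_percent <= 1))
  expect_true(all(res$steps$bend_duration_total <=
                    res$steps$step_duration + 1e-9))
})
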