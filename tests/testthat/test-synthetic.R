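shape <- fish_shape()

test_that("an unbent fish renders mirror-symmetric about the heading axis", {
  h <- 361                                  # odd height: exact mirror axis
  pose <- fish_pose(c(240, 181), heading = 0, bend_amplitude = 0)
  fr <- render_fish_mask(shape, pose, c(480, h))
  flipped <- fr$body_mask[, h:1]
  expect_identical(fr$body_mask, flipped)
  ## true midline collinear
  expect_true(all(abs(fr$midline[, "y"] - 181) < 1e-9))
})

test_that("the true midline landmarks carry the posed bend angle and onset", {
  for (amp_deg in c(-25, 0, 12, 20)) {
    pose <- fish_pose(c(240, 180), heading = 0.7,
                      bend_amplitude = amp_deg * pi / 180, bend_onset = 0.75)
    ml <- fishgait:::fish_midline(shape, pose)
    P <- fishgait:::true_midline_points(ml, 10)
    ## recovered alpha up to the chord bias of landmark decimation: the
    ## caudal chord S1-S2 spans L/10 of a uniformly curved arc, so it
    ## under-reads the tail tangent by kappa * L/20 = amp / 15 here
    a <- wrapped_delta(segment_orientation(P[9, ], P[10, ]),
                       segment_orientation(P[1, ], P[2, ]))
    expect_equal(a, amp_deg * pi / 180 * (1 - 1 / 15),
                 tolerance = 0.7 * pi / 180)
    if (abs(amp_deg) >= 20) {
      ## on a uniformly curved bend the flexion-onset rule reads proximal
      ## of the scripted onset by ~ tolerance * s_bend / |amp|
      k <- bend_position(P, tolerance = 10 * pi / 180)
      bias <- 10 / abs(amp_deg) * 0.75
      expect_lte(k, 0.78)
      expect_gte(k, 0.75 - bias - 0.12)
    }
  }
})

test_that("rendering round trip recovers alpha from the true midline within 1 degree", {
  ## finer tolerance on the dense midline itself (no landmark decimation)
  for (amp_deg in c(-30, 15, 28)) {
    pose <- fish_pose(c(240, 180), heading = -0.3,
                      bend_amplitude = amp_deg * pi / 180, bend_onset = 0.6)
    ml <- fishgait:::fish_midline(shape, pose, n_samples = 600)
    m <- nrow(ml)
    caud <- segment_orientation(ml[1, 1:2], ml[2, 1:2])
    cran <- segment_orientation(ml[m - 1, 1:2], ml[m, 1:2])
    expect_equal(wrapped_delta(cran, caud), amp_deg * pi / 180,
                 tolerance = 1 * pi / 180)
  }
})

test_that("out-of-canvas poses are rejected", {
  expect_error(render_fish_mask(shape, fish_pose(c(10, 10)), c(480, 360)),
               "canvas")
})

test_that("video rendering is deterministic and frame-exact", {
  sc <- random_swim_script(seed = 3, duration = 1, fps = 100, n_steps = 1)
  v1 <- render_swim_video(shape, sc, canvas = c(480, 360), noise_sd = 1)
  v2 <- render_swim_video(shape, sc, canvas = c(480, 360), noise_sd = 1)
  expect_length(v1$frames, 100)             # duration x fps
  expect_identical(v1$truth, v2$truth)
  expect_identical(v1$frames, v2$frames)
})

test_that("ground-truth step count equals the scripted event count", {
  sc <- random_swim_script(seed = 11, duration = 6, fps = 100, n_steps = 5)
  expect_equal(nrow(sc$events), 5)
  sim <- simulate_kinematics(sc)
  expect_equal(nrow(sim$truth$steps), 5)
  ## every ground-truth episode lies within its scripted event's support
  for (tab in sim$truth[c("bends", "turns", "accels")]) {
    ev <- sc$events[tab$step, ]
    t0 <- round(ev$t_start * 100)
    t1 <- round((ev$t_start + ev$n_bends / (2 * ev$bend_freq) /
                   (1 - ev$coast_frac)) * 100)
    expect_true(all(tab$start_frame >= t0 - 1e-9))
    expect_true(all(tab$end_frame <= t1 + 1e-9))
  }
})

test_that("scripted bend trains have the stated amplitude and frequency", {
  ev <- data.frame(t_start = 0.2, n_bends = 2, bend_freq = 10,
                   peak_bend = 20 * pi / 180, turn_angle = 0,
                   speed_gain = 40, coast_frac = 0.5, bend_onset = 0.6)
  sc <- swim_script(2, 100, ev, v0 = 3)
  sim <- simulate_kinematics(sc)
  expect_equal(max(sim$series$alpha), 20 * pi / 180, tolerance = 1e-9)
  ## alpha returns to 0 after the step and stays there
  expect_true(all(abs(sim$series$alpha[sim$series$t > 0.31]) < 1e-9))
  ## zero-crossing-counted frequency of a long bend train: ~ scripted rate
  ev2 <- data.frame(t_start = 0.1, n_bends = 40, bend_freq = 20,
                    peak_bend = 25 * pi / 180, turn_angle = 0,
                    speed_gain = 40, coast_frac = 0.3, bend_onset = 0.6)
  sim2 <- simulate_kinematics(swim_script(2, 400, ev2, v0 = 3))
  a <- sim2$series$alpha
  active <- which(abs(a) > 1e-12)
  span <- (max(active) - min(active)) / 400
  crossings <- sum(diff(sign(a[active])) != 0)
  expect_equal(crossings / (2 * span), 20, tolerance = 1)   # within 5 %
})

test_that("an empty script yields a resting fish", {
  ev <- data.frame(t_start = numeric(0), n_bends = numeric(0),
                   bend_freq = numeric(0), peak_bend = numeric(0),
                   turn_angle = numeric(0), speed_gain = numeric(0),
                   coast_frac = numeric(0), bend_onset = numeric(0))
  sim <- simulate_kinematics(swim_script(1, 100, ev, v0 = 0))
  expect_true(all(sim$series$v == 0))
  expect_true(all(sim$series$alpha == 0))
  expect_equal(length(unique(sim$series$theta)), 1)
})

test_that("error injection is labeled, localized and detectable", {
  sc <- random_swim_script(seed = 5, duration = 2, fps = 100, n_steps = 1)
  tr <- simulate_track_series(sc)$track
  ## empty frame set: identity
  out0 <- inject_point_errors(tr, integer(0), "pectoral-fin")
  expect_identical(out0$track$frames, tr$frames)
  expect_length(out0$labels, 0)
  ## labels equal requested frames; untouched frames identical
  inj <- inject_point_errors(tr, c(40, 41, 90), "pectoral-fin")
  expect_identical(inj$labels, c(40L, 41L, 90L))
  touched <- tr$frames$frame %in% inj$labels
  expect_identical(inj$track$frames[!touched, ], tr$frames[!touched, ])
  expect_false(identical(inj$track$frames[touched, ], tr$frames[touched, ]))
  ## pectoral-fin mode on a straight-swimming track: caudal jump >= 57 deg
  ev0 <- data.frame(t_start = numeric(0), n_bends = numeric(0),
                    bend_freq = numeric(0), peak_bend = numeric(0),
                    turn_angle = numeric(0), speed_gain = numeric(0),
                    coast_frac = numeric(0), bend_onset = numeric(0))
  trs <- simulate_track_series(swim_script(1, 100, ev0, v0 = 10))$track
  injs <- inject_point_errors(trs, 40, "pectoral-fin")
  so1 <- segment_orientations(injs$track)
  d12 <- abs(wrapped_delta(so1$theta12[40], so1$theta12[41]))
  expect_gte(d12, 57 * pi / 180)
  expect_error(inject_point_errors(tr, c(9999), "tail-fin"), "exist")
})
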