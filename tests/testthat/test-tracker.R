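test_that("background estimation is a per-pixel median", {
  f <- matrix(230, 40, 30)
  expect_identical(estimate_background(list(f, f, f)), f)
  ## three frames with pixel values {1, 2, 9} -> 2
  a <- matrix(1, 4, 4); b <- matrix(2, 4, 4); d <- matrix(9, 4, 4)
  expect_true(all(estimate_background(list(a, b, d)) == 2))
  ## a fish present in < half the samples leaves the true arena everywhere
  bg <- matrix(200, 40, 30)
  stack <- lapply(1:5, function(i) {
    fr <- bg
    if (i <= 2) fr[(i * 5):(i * 5 + 3), 10:14] <- 30   # moving dark blob
    fr
  })
  expect_identical(estimate_background(stack), bg)
  expect_error(estimate_background(list(a, b)), "at least 3")
  expect_error(estimate_background(list(a, b, matrix(0, 3, 3))),
               "inconsistent")
})

test_that("mask centroid is the mean of foreground coordinates", {
  m <- matrix(FALSE, 20, 20)
  m[7, 4] <- TRUE
  expect_equal(mask_centroid(m), c(7, 4))
  m2 <- matrix(FALSE, 20, 20)
  m2[1:3, 1:3] <- TRUE                      # corner (1,1) 3x3 square
  expect_equal(mask_centroid(m2), c(2, 2))
  ## L-shape vs brute force over enumerated pixels
  m3 <- matrix(FALSE, 30, 30)
  m3[5:20, 5:8] <- TRUE
  m3[5:9, 9:22] <- TRUE
  idx <- which(m3, arr.ind = TRUE)
  expect_equal(mask_centroid(m3), c(mean(idx[, 1]), mean(idx[, 2])))
  expect_error(mask_centroid(matrix(FALSE, 3, 3)), "empty")
})

test_that("the tail is the sharpest contour point", {
  ## isoceles triangle: apex at (40, 15), base at x = 10
  tri <- mask_from(60, 30, function(x, y)
    x >= 10 & x <= 40 & abs(y - 15) <= (40 - x) / 3)
  lc <- fishgait:::largest_component_contour(tri)
  i <- locate_tail(lc$contour, lc$mask, 7)
  apex <- attr(i, "point")
  ## exhaustive window sums over the contour agree
  ws <- fishgait:::window_counts(lc$mask, lc$contour, 3)
  expect_equal(ws[i], min(ws))
  expect_lt(sqrt(sum((apex - c(40, 15))^2)), 2.5)
  expect_false(attr(i, "low_confidence"))
  ## a circle ties everywhere: first contour index, low confidence
  circ <- mask_from(40, 40, function(x, y) (x - 20)^2 + (y - 20)^2 <= 144)
  lc2 <- fishgait:::largest_component_contour(circ)
  i2 <- locate_tail(lc2$contour, lc2$mask, 5)
  expect_true(attr(i2, "low_confidence"))
  ws2 <- fishgait:::window_counts(lc2$mask, lc2$contour, 2)
  expect_identical(as.integer(i2), which.min(ws2))
  expect_error(locate_tail(lc2$contour[1:4, ], lc2$mask, 5), "degenerate")
})

test_that("the head is the sharpest point of the proximal half", {
  ## symmetric capsule: two identical ends; head must be opposite S1
  cap <- capsule_mask(100, 40, 25, 75, 20, 8)
  lc <- fishgait:::largest_component_contour(cap)
  i_tail <- locate_tail(lc$contour, lc$mask, 7)
  i_head <- locate_head(lc$contour, lc$mask, i_tail, 7)
  p_tail <- attr(i_tail, "point")
  p_head <- attr(i_head, "point")
  expect_gt(sqrt(sum((p_head - p_tail)^2)), 45)
})

test_that("midline points of a straight capsule lie on the axis", {
  ## slender capsule: the end caps consume little contour arc, so equal
  ## arc fractions also mean near-equal spacing of the interior points
  cap <- capsule_mask(140, 50, 20, 120, 25, 4)
  lc <- fishgait:::largest_component_contour(cap)
  i_tail <- locate_tail(lc$contour, lc$mask, 7)
  i_head <- locate_head(lc$contour, lc$mask, i_tail, 7)
  P <- midline_points(lc$contour, i_tail, i_head, 5)
  expect_equal(nrow(P), 6)
  expect_true(all(abs(P[2:5, 2] - 25) <= 1))          # on the central axis
  gaps <- sqrt(rowSums(diff(P[2:5, ])^2))             # interior spacing
  expect_lt(max(abs(gaps - mean(gaps))), 1)
  ## unequal arcs still return the contracted number of points
  P2 <- midline_points(lc$contour, i_tail,
                       i_head + 5L, 7)
  expect_equal(dim(P2), c(8, 2))
})

test_that("juvenile tail refinement picks a more distal caudal point", {
  ## direct channel: short body; subtraction channel: body + light tail
  body <- capsule_mask(120, 40, 40, 90, 20, 7)
  with_tail <- body | capsule_mask(120, 40, 18, 90, 20, 2.5)
  lc <- fishgait:::largest_component_contour(body)
  i_tail <- locate_tail(lc$contour, lc$mask, 7)
  s1 <- attr(i_tail, "point")
  head <- c(97, 20)
  s0 <- refine_tail_juvenile(with_tail, s1, head, 7)
  expect_true(attr(s0, "refined"))
  d1 <- sqrt(sum((s1 - head)^2))
  d0 <- sqrt(sum((s0 - head)^2))
  expect_gt(d0, d1)                                   # strictly more distal
  ## identical masks: nothing distal of S1 remains -> S1 kept
  s_same <- refine_tail_juvenile(body, s1, head, 7)
  expect_false(attr(s_same, "refined"))
  expect_equal(as.numeric(s_same), as.numeric(s1))
  ## pectoral lobes in the subtraction channel are proximal to S1: excluded
  with_fins <- with_tail |
    mask_from(120, 40, function(x, y) (x - 70)^2 + (y - 8)^2 <= 16) |
    mask_from(120, 40, function(x, y) (x - 70)^2 + (y - 32)^2 <= 16)
  s0f <- refine_tail_juvenile(with_fins, s1, head, 7)
  expect_lt(sqrt(sum((s0f - c(16, 20))^2)), 4)        # true light tail tip
})

test_that("tracked synthetic video recovers the true posture", {
  shape <- fish_shape()
  sc <- random_swim_script(seed = 31, duration = 0.6, fps = 100, n_steps = 1)
  vid <- render_swim_video(shape, sc, canvas = c(480, 360))
  tr <- track_video(vid$frames, tracker_params("adult"), fps = 100,
                    mm_per_px = 0.25)
  expect_equal(nrow(tr$frames), 60)
  expect_true(all(tr$frames$flag == "ok"))
  errs <- c()
  for (i in seq_len(60)) {
    P <- fishgait:::midline_points_of_row(tr$frames[i, ], 10)
    errs <- c(errs, vapply(1:11, function(j)
      fishgait:::point_polyline_distance(P[j, ], vid$truth$points[i, , ]), 0))
    ## ordering: arc distance from S1 strictly increases along the midline
    expect_true(all(diff(cumsum(c(0, sqrt(rowSums(diff(P)^2))))) > 0))
  }
  expect_lte(median(errs), 1)
  expect_lte(max(errs), 3)
  ## centroid within 1 px of the true silhouette centroid
  ce <- sqrt((tr$frames$cx - vid$truth$frames$cx)^2 +
               (tr$frames$cy - vid$truth$frames$cy)^2)
  expect_lt(max(ce), 1)
})

test_that("blank frames are flagged no_fish without shortening the series", {
  shape <- fish_shape()
  sc <- random_swim_script(seed = 13, duration = 0.2, fps = 100, n_steps = 1)
  vid <- render_swim_video(shape, sc, canvas = c(480, 360))
  frames <- vid$frames
  frames[[5]] <- matrix(230, 480, 360)                # empty arena
  frames[[11]] <- matrix(230, 480, 360)
  tr <- track_video(frames, tracker_params("adult"), fps = 100,
                    mm_per_px = 0.25)
  expect_equal(nrow(tr$frames), 20)
  expect_identical(tr$frames$flag[c(5, 11)], c("no_fish", "no_fish"))
  expect_true(all(tr$frames$flag[-c(5, 11)] == "ok"))
})

test_that("larva mode tracks a faint fish via background subtraction", {
  ## larva-gray body (180) on a 230 background is invisible to direct
  ## thresholding margins but clear in the difference image
  shape <- fish_shape(body_gray = 180, vignette = 0, fins = FALSE)
  pose <- fish_pose(c(240, 180), heading = 0.2)
  fr <- render_fish_mask(shape, pose, c(480, 360))
  bg <- matrix(230, 480, 360)
  bin <- binarize_frame(fr$img, tracker_params("larva"), background = bg)
  expect_false(isTRUE(bin$no_fish))
  lc <- fishgait:::largest_component_contour(bin$mask)
  expect_gt(lc$area, 0.5 * sum(fr$body_mask))         # contiguous body
  expect_lt(lc$area, 2 * sum(fr$body_mask))
})

test_that("calibration follows the arena geometry", {
  expect_equal(calibrate_mm_per_px(110, 440), 0.25)
  expect_error(calibrate_mm_per_px(0, 10))
})
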