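#' Whole-recording macro-parameters
#'
#' Aggregates a kinematic series and its episodes into the macro-parameters
#' of a recording: distance traveled, freezing, active speed, maximum speed,
#' thigmotaxis, meandering, and the counts/totals (with left/right splits)
#' of turns, bends and steps.
#'
#' Freezing is the total time in runs where the smoothed speed stays below
#' `freeze_speed` for at least `freeze_min_duration`; active speed is the
#' mean speed outside freezing; meandering is the summed |turn angle| per
#' active (non-freezing) second. Thigmotaxis is the time the centroid spends
#' within `wall_band_mm` of the arena polygon boundary (NA when no arena or
#' positions are supplied).
#'
#' @param kin A `kinematic_series`.
#' @param bends,turns,steps Episode/step tables from the detectors.
#' @param positions Optional n x 2 centroid positions in px (for
#'   thigmotaxis).
#' @param arena Optional arena polygon, m x 2 px (closed implicitly).
#' @param wall_band_mm Width of the wall band in mm (commonly one body
#'   length).
#' @param thresholds A [gait_thresholds()] list.
#' @return One-row data.frame of macro-parameters; times s, distances mm,
#'   angles rad.
#' @export
macro_summary <- function(kin, bends, turns, steps, positions = NULL,
                          arena = NULL, wall_band_mm = 30,
                          thresholds = gait_thresholds()) {
  fps <- attr(kin, "fps")
  mmpx <- attr(kin, "mm_per_px")
  n <- nrow(kin)
  dt <- 1 / fps
  v <- kin$v
  distance <- sum(v, na.rm = TRUE) * dt
  ## freezing runs on the smoothed speed
  frozen <- kin$v_smooth < thresholds$freeze_speed
  frozen[is.na(frozen)] <- FALSE
  r <- rle(frozen)
  keep <- r$values & r$lengths >= thresholds$freeze_min_duration * fps
  freeze_mask <- inverse.rle(list(values = keep, lengths = r$lengths))
  freezing <- sum(freeze_mask) * dt
  active_time <- (n - sum(freeze_mask)) * dt
  active_speed <- if (any(!freeze_mask)) mean(v[!freeze_mask], na.rm = TRUE)
                  else 0
  thigmo <- NA_real_
  if (!is.null(positions) && !is.null(arena)) {
    band_px <- wall_band_mm / mmpx
    d <- polygon_boundary_distance(positions, arena)
    thigmo <- sum(d <= band_px, na.rm = TRUE) * dt
  }
  lr <- function(df, col, dircol = "direction") {
    if (nrow(df) == 0) return(c(left = 0, right = 0))
    c(left = sum(abs(df[[col]][df[[dircol]] == "left"]), na.rm = TRUE),
      right = sum(abs(df[[col]][df[[dircol]] == "right"]), na.rm = TRUE))
  }
  turn_ang <- lr(turns, "angle")
  turn_dur <- lr(turns, "duration")
  bend_ang <- lr(bends, "delta")
  bend_dur <- lr(bends, "duration")
  data.frame(
    distance_traveled = distance,
    freezing = freezing,
    active_speed = active_speed,
    max_speed = max(v, na.rm = TRUE),
    thigmotaxis_duration = thigmo,
    meandering = if (active_time > 0)
      sum(abs(turns$angle)) / active_time else NA_real_,
    turn_count = nrow(turns),
    turn_count_left = sum(turns$direction == "left"),
    turn_count_right = sum(turns$direction == "right"),
    total_turn_angle = sum(abs(turns$angle)),
    total_turn_angle_left = unname(turn_ang["left"]),
    total_turn_angle_right = unname(turn_ang["right"]),
    total_turn_duration = sum(turns$duration),
    total_turn_duration_left = unname(turn_dur["left"]),
    total_turn_duration_right = unname(turn_dur["right"]),
    bend_count = nrow(bends),
    bend_count_left = sum(bends$direction == "left"),
    bend_count_right = sum(bends$direction == "right"),
    total_bend_angle = sum(abs(bends$delta)),
    total_bend_angle_left = unname(bend_ang["left"]),
    total_bend_angle_right = unname(bend_ang["right"]),
    total_bend_duration = sum(bends$duration),
    total_bend_duration_left = unname(bend_dur["left"]),
    total_bend_duration_right = unname(bend_dur["right"]),
    step_count = nrow(steps))
}

## distance from each point to the nearest edge of a polygon (px)
polygon_boundary_distance <- function(points, poly) {
  m <- nrow(poly)
  poly2 <- rbind(poly, poly[1, ])
  vapply(seq_len(nrow(points)), function(i)
    point_polyline_distance(as.numeric(points[i, ]), poly2), 0)
}
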