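## Episode segmentation: tail bends, turns, accelerations, and their
## grouping into burst-and-coast steps.

#' Default episode-detection thresholds
#'
#' All angles rad, times s, speeds mm/s. The defaults are small relative to
#' normal rapid swimming dynamics at 100 fps (per-frame cranial orientation
#' changes reach 40 deg) so that genuine episodes are kept while derivative
#' noise is rejected.
#'
#' @param min_bend_amplitude Minimum |bend angle change| of a tail sweep.
#' @param turn_rate_threshold Orientation rate (rad/s) defining a turn.
#' @param min_turn_angle Minimum |turn angle|.
#' @param turn_merge_gap Frames of sub-threshold rate merged across.
#' @param min_speed_change Minimum speed rise of an acceleration episode.
#' @param quiescence_frames Consecutive frames within half the amplitude
#'   threshold of a resting anchor that close a sweep (noise-robust
#'   stationarity test).
#' @param inter_bend_gap Maximum time (s) between consecutive bends of one
#'   burst.
#' @param freeze_speed,freeze_min_duration Freezing definition: speed below
#'   `freeze_speed` sustained for at least `freeze_min_duration`.
#' @return A list of thresholds.
#' @export
gait_thresholds <- function(min_bend_amplitude = 5 * pi / 180,
                            turn_rate_threshold = 30 * pi / 180,
                            min_turn_angle = 10 * pi / 180,
                            turn_merge_gap = 2,
                            min_speed_change = 5,
                            quiescence_frames = 5,
                            inter_bend_gap = 0.15,
                            freeze_speed = 1,
                            freeze_min_duration = 1) {
  as.list(environment())
}

## Generic monotone-sweep extraction (zigzag filter).
## Returns data.frame(start, end, extreme, delta) of maximal monotone sweeps
## between significant reversals; indices are 1-based into x.
extract_sweeps <- function(x, fps, min_amp, quiescence_frames) {
  n <- length(x)
  sweeps <- list()
  dirn <- 0L
  ref_min <- ref_max <- x[1]
  ref_min_i <- ref_max_i <- 1L
  start_i <- 1L
  ext <- x[1]; ext_i <- 1L
  quiet <- 0L
  anchor <- x[1]
  band <- min_amp / 2        # quiescence: signal pinned within +-band
  eps <- 0.02 * min_amp      # near-tie tolerance: rest plateaus advance the
                             # reference index instead of pinning it to noise
  close_sweep <- function(s, e) {
    if (e > s && abs(x[e] - x[s]) >= min_amp)
      sweeps[[length(sweeps) + 1]] <<-
        data.frame(start = s, end = e, delta = x[e] - x[s])
  }
  for (i in 2:n) {
    if (is.na(x[i])) { quiet <- quiet + 1L; next }
    if (abs(x[i] - anchor) <= band) quiet <- quiet + 1L
    else { anchor <- x[i]; quiet <- 0L }
    if (dirn == 0L) {
      if (quiet >= quiescence_frames) {
        ## sustained rest: re-centre the references so that slow noise
        ## drift can never accumulate into a spurious sweep trigger
        ref_min <- ref_max <- x[i]
        ref_min_i <- ref_max_i <- i
        quiet <- 0L
      }
      if (x[i] <= ref_min + eps) { ref_min <- min(ref_min, x[i]); ref_min_i <- i }
      if (x[i] >= ref_max - eps) { ref_max <- max(ref_max, x[i]); ref_max_i <- i }
      if (x[i] - ref_min >= min_amp) {
        dirn <- 1L; start_i <- ref_min_i; ext <- x[i]; ext_i <- i
      } else if (ref_max - x[i] >= min_amp) {
        dirn <- -1L; start_i <- ref_max_i; ext <- x[i]; ext_i <- i
      }
    } else {
      if (dirn * (x[i] - ext) > eps) { ext <- x[i]; ext_i <- i }
      if (dirn * (ext - x[i]) >= min_amp) {
        ## reversal: close at the extreme and start the opposite sweep
        close_sweep(start_i, ext_i)
        dirn <- -dirn
        start_i <- ext_i
        ext <- x[i]; ext_i <- i
        anchor <- x[i]; quiet <- 0L
      } else if (quiet >= quiescence_frames) {
        ## the signal came to rest: close at the last extreme, which also
        ## seeds the references so the next sweep starts from it
        close_sweep(start_i, ext_i)
        dirn <- 0L
        ref_min <- ref_max <- ext
        ref_min_i <- ref_max_i <- ext_i
        anchor <- x[i]; quiet <- 0L
      }
    }
  }
  if (dirn != 0L) close_sweep(start_i, ext_i)
  if (length(sweeps) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      delta = numeric(0)))
  do.call(rbind, sweeps)
}

#' Detect tail-bend episodes
#'
#' Bends are maximal monotone sweeps of the bend angle between successive
#' significant extrema (or departures from rest), with
#' `|delta alpha| >= min_bend_amplitude`. Direction follows the sign of the
#' change (positive = left).
#'
#' @param kin A `kinematic_series` from [derive_series()] (or any data.frame
#'   with `alpha`, `k` and attribute `fps`).
#' @param thresholds A [gait_thresholds()] list.
#' @return data.frame: start_frame, end_frame (0-based), delta (rad),
#'   direction ("left"/"right"), angular_velocity (max |d alpha/dt|, rad/s),
#'   duration (s), bend_position (max k within the sweep, NA if undefined).
#' @export
detect_bends <- function(kin, thresholds = gait_thresholds()) {
  fps <- attr(kin, "fps")
  ## boundaries are found on a lightly smoothed series (sub-pixel posture
  ## jitter otherwise fragments sweeps), then snapped to the raw extremum
  ## within one frame; amplitudes are always measured on the raw series
  alpha_s <- moving_average(kin$alpha, 3)
  sw <- extract_sweeps(alpha_s, fps, thresholds$min_bend_amplitude,
                       thresholds$quiescence_frames)
  if (nrow(sw) > 0) {
    n <- length(kin$alpha)
    tol <- 0.02 * thresholds$min_bend_amplitude
    snap <- function(j, want_max, latest) {
      lo <- max(1, j - 1); hi <- min(n, j + 1)
      seg <- kin$alpha[lo:hi]
      seg[is.na(seg)] <- if (want_max) -Inf else Inf
      cand <- if (want_max) which(seg >= max(seg) - tol)
              else which(seg <= min(seg) + tol)
      lo + (if (latest) max(cand) else min(cand)) - 1
    }
    for (r in seq_len(nrow(sw))) {
      up <- sw$delta[r] > 0
      s <- snap(sw$start[r], want_max = !up, latest = TRUE)
      e <- snap(sw$end[r], want_max = up, latest = FALSE)
      if (e > s) { sw$start[r] <- s; sw$end[r] <- e }
      sw$delta[r] <- kin$alpha[sw$end[r]] - kin$alpha[sw$start[r]]
    }
    sw <- sw[abs(sw$delta) >= thresholds$min_bend_amplitude, , drop = FALSE]
  }
  if (nrow(sw) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      delta = numeric(0), direction = character(0),
                      angular_velocity = numeric(0), duration = numeric(0),
                      bend_position = numeric(0)))
  out <- lapply(seq_len(nrow(sw)), function(r) {
    i0 <- sw$start[r]; i1 <- sw$end[r]
    da <- abs(diff(kin$alpha[i0:i1])) * fps
    kk <- kin$k[i0:i1]
    data.frame(start_frame = kin$frame[i0], end_frame = kin$frame[i1],
               delta = sw$delta[r],
               direction = if (sw$delta[r] > 0) "left" else "right",
               angular_velocity = max(da, na.rm = TRUE),
               duration = (i1 - i0) / fps,
               bend_position = if (all(is.na(kk))) NA_real_
                               else max(kk, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Detect turning episodes
#'
#' Maximal intervals where the orientation rate exceeds
#' `turn_rate_threshold`, merged across gaps of at most `turn_merge_gap`
#' frames, kept when the net orientation change reaches `min_turn_angle`.
#'
#' @inheritParams detect_bends
#' @return data.frame: start_frame, end_frame, angle (rad, theta end minus
#'   theta start), direction ("right" if positive: a clockwise heading
#'   change as printed is a turn to the fish's right), angular_velocity
#'   (max |d theta/dt|), duration (s).
#' @export
detect_turns <- function(kin, thresholds = gait_thresholds()) {
  fps <- attr(kin, "fps")
  th <- kin$theta
  n <- length(th)
  none <- data.frame(start_frame = integer(0), end_frame = integer(0),
                     angle = numeric(0), direction = character(0),
                     angular_velocity = numeric(0), duration = numeric(0))
  if (n < 2) return(none)
  rate <- abs(diff(th)) * fps
  active <- rate > thresholds$turn_rate_threshold
  active[is.na(active)] <- FALSE
  if (!any(active)) return(none)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  ## merge across short inactive gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1 <= thresholds$turn_merge_gap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  out <- lapply(seq_len(nrow(merged)), function(r_) {
    i0 <- merged$start[r_]          # transition index = frame row i0 -> i0+1
    i1 <- merged$end[r_] + 1
    ang <- th[i1] - th[i0]
    data.frame(start_frame = kin$frame[i0], end_frame = kin$frame[i1],
               angle = ang,
               direction = if (ang > 0) "right" else "left",
               angular_velocity = max(rate[merged$start[r_]:merged$end[r_]],
                                      na.rm = TRUE),
               duration = (i1 - i0) / fps)
  })
  out <- do.call(rbind, out)
  out[abs(out$angle) >= thresholds$min_turn_angle, , drop = FALSE]
}

#' Detect acceleration episodes
#'
#' Maximal rises of the smoothed speed from a local trough to the following
#' local peak with a speed change of at least `min_speed_change`.
#'
#' @inheritParams detect_bends
#' @return data.frame: start_frame, end_frame, speed_change (mm/s),
#'   acceleration (max dv/dt, mm/s^2), duration (s).
#' @export
detect_accels <- function(kin, thresholds = gait_thresholds()) {
  fps <- attr(kin, "fps")
  sw <- extract_sweeps(kin$v_smooth, fps, thresholds$min_speed_change,
                       thresholds$quiescence_frames)
  sw <- sw[sw$delta > 0, , drop = FALSE]
  if (nrow(sw) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      speed_change = numeric(0), acceleration = numeric(0),
                      duration = numeric(0)))
  out <- lapply(seq_len(nrow(sw)), function(r) {
    i0 <- sw$start[r]; i1 <- sw$end[r]
    dv <- diff(kin$v_smooth[i0:i1]) * fps
    data.frame(start_frame = kin$frame[i0], end_frame = kin$frame[i1],
               speed_change = sw$delta[r],
               acceleration = max(dv, na.rm = TRUE),
               duration = (i1 - i0) / fps)
  })
  do.call(rbind, out)
}

#' Assemble episodes into burst-and-coast steps
#'
#' Consecutive bends separated by no more than `inter_bend_gap` form the
#' bend series of one step; its time support is the burst. Turns and
#' accelerations overlapping the burst are attached. The coast extends from
#' the burst end to the next step's burst start; the final step coasts until
#' the smoothed speed stops decaying (its local trough), freezing begins, or
#' the series ends. Steps inherit the step micro-parameters: the attached
#' acceleration's speed change and peak slope, the attached turn's angle,
#' peak rate and duration, and the bend summary of the sweep series (maximum
#' bend angle reached, total angle traveled, peak angular velocity, total
#' bend duration, wave frequency = bend count / total bend duration), plus
#' coast duration, step duration, coast percent and step length
#' (integral of v over the step).
#'
#' @param bends,turns,accels Episode tables from the detectors.
#' @param kin The `kinematic_series` they came from.
#' @param thresholds A [gait_thresholds()] list.
#' @return data.frame with one row per step; times s, angles rad, speeds
#'   mm/s, lengths mm. `n_bends` counts member sweeps.
#' @export
assemble_steps <- function(bends, turns, accels, kin,
                           thresholds = gait_thresholds()) {
  fps <- attr(kin, "fps")
  cols <- c("start_frame", "burst_end_frame", "end_frame", "n_bends",
            "speed_change", "acceleration", "turn_angle",
            "turn_angular_velocity", "turn_duration", "bend_angle_reached",
            "bend_angle_traveled", "bend_angular_velocity",
            "bend_duration_total", "bend_wave_frequency", "bend_position",
            "coast_duration", "step_duration", "coast_percent", "step_length",
            "bend_direction", "turn_direction")
  if (nrow(bends) == 0)
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols))
  bends <- bends[order(bends$start_frame), , drop = FALSE]
  gap_frames <- thresholds$inter_bend_gap * fps
  grp <- if (nrow(bends) == 1) 1 else
    cumsum(c(1, (bends$start_frame[-1] -
                   bends$end_frame[-nrow(bends)]) > gap_frames))
  groups <- split(seq_len(nrow(bends)), grp)
  n_steps <- length(groups)
  out <- vector("list", n_steps)
  burst_starts <- vapply(groups, function(g) bends$start_frame[g[1]], 0)
  for (s in seq_len(n_steps)) {
    g <- groups[[s]]
    bs <- bends[g, , drop = FALSE]
    b0 <- bs$start_frame[1]
    b1 <- bs$end_frame[nrow(bs)]
    ## coast end
    if (s < n_steps) {
      e1 <- burst_starts[s + 1]
    } else {
      i1 <- match(b1, kin$frame)
      vs <- kin$v_smooth
      e1 <- kin$frame[length(vs)]
      if (i1 < length(vs) - 1) {
        after <- (i1 + 1):length(vs)
        dv <- c(diff(vs[after]), 0)
        frozen <- vs[after] < thresholds$freeze_speed
        stopd <- which(dv >= 0 | frozen)
        if (length(stopd)) e1 <- kin$frame[after[stopd[1]]]
      }
    }
    ib <- match(b0, kin$frame):match(b1, kin$frame)
    istep <- match(b0, kin$frame):match(e1, kin$frame)
    ov_t <- turns[turns$start_frame <= b1 & turns$end_frame >= b0, ,
                  drop = FALSE]
    ov_a <- accels[accels$start_frame <= b1 & accels$end_frame >= b0, ,
                   drop = FALSE]
    ## a lone sweep that drives neither an acceleration nor a turn is not
    ## a step; it stays an unassigned bend
    if (nrow(bs) == 1 && nrow(ov_t) == 0 && nrow(ov_a) == 0) next
    tpick <- if (nrow(ov_t)) ov_t[which.max(abs(ov_t$angle)), ] else NULL
    apick <- if (nrow(ov_a)) ov_a[which.max(ov_a$speed_change), ] else NULL
    bd_total <- sum(bs$duration)
    vstep <- kin$v[istep]
    step_len <- sum((vstep[-1] + vstep[-length(vstep)]) / 2, na.rm = TRUE) / fps
    dur <- (e1 - b0) / fps
    coast <- (e1 - b1) / fps
    dirs <- table(bs$direction)
    out[[s]] <- data.frame(
      start_frame = b0, burst_end_frame = b1, end_frame = e1,
      n_bends = nrow(bs),
      speed_change = if (is.null(apick)) NA_real_ else apick$speed_change,
      acceleration = if (is.null(apick)) NA_real_ else apick$acceleration,
      turn_angle = if (is.null(tpick)) NA_real_ else tpick$angle,
      turn_angular_velocity = if (is.null(tpick)) NA_real_
                              else tpick$angular_velocity,
      turn_duration = if (is.null(tpick)) NA_real_ else tpick$duration,
      bend_angle_reached = max(abs(kin$alpha[ib]), na.rm = TRUE),
      bend_angle_traveled = sum(abs(bs$delta)),
      bend_angular_velocity = max(bs$angular_velocity),
      bend_duration_total = bd_total,
      bend_wave_frequency = nrow(bs) / bd_total,
      bend_position = if (all(is.na(bs$bend_position))) NA_real_
                      else max(bs$bend_position, na.rm = TRUE),
      coast_duration = coast,
      step_duration = dur,
      coast_percent = coast / dur,
      step_length = step_len,
      bend_direction = names(dirs)[which.max(dirs)],
      turn_direction = if (is.null(tpick)) NA_character_ else tpick$direction)
  }
  do.call(rbind, out)
}
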