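#' Rotating-drum arena geometry
#'
#' Dimensions of the walking arena: an outer rotating pattern drum, an
#' inner stationary translucent cylinder, and a central circular walking
#' container. Defaults correspond to a 190 mm diameter drum, 140 mm inner
#' cylinder and 30 mm walking container filmed at 60 frames/s, so the
#' animal-to-pattern distance ranges from 80 to 110 mm and the drum
#' circumference is 0.597 m.
#'
#' @param drum_radius Pattern drum radius, mm.
#' @param inner_cylinder_radius Inner stationary cylinder radius, mm.
#' @param container_radius Walking container radius, mm.
#' @param frame_rate Video frame rate, Hz.
#' @return An object of class `arena_geometry` with derived fields
#'   `min_pattern_distance`, `max_pattern_distance` (mm) and
#'   `drum_circumference` (metres).
#' @export
arena_geometry <- function(drum_radius = 95, inner_cylinder_radius = 70,
                           container_radius = 15, frame_rate = 60) {
  stop_field(container_radius < inner_cylinder_radius &&
               inner_cylinder_radius < drum_radius,
             "radii", "require container < inner cylinder < drum")
  stop_field(frame_rate > 0, "frame_rate", "must be positive")
  structure(list(drum_radius = drum_radius,
                 inner_cylinder_radius = inner_cylinder_radius,
                 container_radius = container_radius,
                 frame_rate = frame_rate,
                 min_pattern_distance = drum_radius - container_radius,
                 max_pattern_distance = drum_radius + container_radius,
                 drum_circumference = pi * 2 * drum_radius / 1000),
            class = "arena_geometry")
}

#' Grating stimulus descriptor
#'
#' @param wavelength Spatial wavelength of the stripe grating, degrees
#'   (> 0).
#' @param velocity Drum angular velocity, deg/s; its sign encodes rotation
#'   direction.
#' @return An object of class `stimulus_condition` with derived
#'   `temporal_frequency = velocity / wavelength` (Hz, signed) and
#'   `direction` (+1/-1).
#' @export
stimulus_condition <- function(wavelength, velocity) {
  stop_field(wavelength > 0, "wavelength", "must be positive (degrees)")
  structure(list(wavelength = wavelength, velocity = velocity,
                 temporal_frequency = velocity / wavelength,
                 direction = if (velocity >= 0) 1 else -1),
            class = "stimulus_condition")
}

traj_frame_rate <- function(traj) {
  dt <- diff(traj$t)
  stop_field(length(dt) >= 1 && all(dt > 0), "traj",
             "time stamps must be strictly increasing")
  1 / stats::median(dt)
}

traj_speed <- function(traj) {
  dt <- diff(traj$t)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  c(step / dt, 0)  # per-frame speed; last frame has no forward interval
}

#' Trajectory quality filters
#'
#' Flags trajectories that should be excluded from response scoring:
#' (1) `"wall_following"` — the radial distance from the container center
#' stays within `wall_epsilon` of the container radius for a contiguous
#' span longer than `max_wall_time`; (2) `"short_walk"` — cumulative time
#' with instantaneous speed above `walk_speed_threshold` is below
#' `min_walk_time`. Both rules are always evaluated, so the flags are
#' independent of rule order.
#'
#' @param traj data.frame with columns `t` (s), `x`, `y` (mm).
#' @param arena An [arena_geometry()].
#' @param walk_speed_threshold Speed above which a frame counts as walking,
#'   mm/s. Speeds are measured from positions smoothed over
#'   `speed_window` and differenced across the same span, so
#'   frame-to-frame tracking jitter does not register as walking.
#' @param wall_epsilon Radial tolerance defining "on the wall", mm.
#' @param max_wall_time Longest tolerated contiguous wall-following span, s.
#' @param min_walk_time Minimum cumulative walking time, s.
#' @param speed_window Smoothing/differencing span for the speed
#'   estimate, s.
#' @param center Container center (mm), default the coordinate origin.
#' @return `traj` with attributes `excluded` (logical) and `exclusion_reasons`
#'   (character vector, possibly empty).
#' @export
apply_exclusion_filters <- function(traj, arena = arena_geometry(),
                                    walk_speed_threshold = 0.5,
                                    wall_epsilon = 0.5,
                                    max_wall_time = 3,
                                    min_walk_time = 10,
                                    speed_window = 0.5,
                                    center = c(0, 0)) {
  stop_field(nrow(traj) >= 2, "traj", "trajectory must have >= 2 frames")
  dt <- diff(traj$t)
  reasons <- character(0)

  r <- sqrt((traj$x - center[1])^2 + (traj$y - center[2])^2)
  on_wall <- abs(r - arena$container_radius) <= wall_epsilon
  runs <- rle(on_wall)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    spans <- vapply(which(runs$values), function(k) {
      traj$t[min(ends[k] + 1L, nrow(traj))] - traj$t[starts[k]]
    }, numeric(1))
    if (any(spans > max_wall_time)) reasons <- c(reasons, "wall_following")
  }

  fr <- traj_frame_rate(traj)
  stride <- max(1L, round(speed_window * fr))
  n <- nrow(traj)
  if (n > stride) {
    xs <- moving_average(traj$x, stride)
    ys <- moving_average(traj$y, stride)
    i <- seq_len(n - stride)
    speed <- sqrt((xs[i + stride] - xs[i])^2 + (ys[i + stride] - ys[i])^2) /
      (traj$t[i + stride] - traj$t[i])
    walking <- speed > walk_speed_threshold
    walk_time <- sum(dt[seq_len(n - stride)][walking])
  } else {
    walk_time <- 0
  }
  if (walk_time < min_walk_time) reasons <- c(reasons, "short_walk")

  attr(traj, "excluded") <- length(reasons) > 0
  attr(traj, "exclusion_reasons") <- reasons
  attr(traj, "walk_time") <- walk_time
  traj
}

#' Detect full-rotation periods from the y-position trace
#'
#' During continuous circling the animal's y-position oscillates with one
#' peak per full 360° body rotation. The trace is smoothed by a centered
#' moving average and local maxima with topographic prominence of at least
#' `min_prominence` are detected; the rotation periods are the successive
#' peak spacings.
#'
#' @param traj data.frame with columns `t`, `x`, `y`.
#' @param smoothing_window Moving-average window, seconds.
#' @param min_prominence Minimum peak prominence, mm.
#' @return An object of class `rotation_segments`: list with `peak_times`
#'   (s), `periods` (s, length `n_peaks - 1`), and `flag`
#'   (`"ok"`/`"no_rotation"`).
#' @export
detect_rotation_periods <- function(traj, smoothing_window = 0.25,
                                    min_prominence = 1) {
  fr <- traj_frame_rate(traj)
  width <- max(1L, round(smoothing_window * fr))
  ysm <- moving_average(traj$y, width)
  peaks <- find_peaks(ysm, min_prominence)
  peak_times <- traj$t[peaks]
  periods <- if (length(peak_times) >= 2) diff(peak_times) else numeric(0)
  structure(list(peak_times = peak_times, periods = periods,
                 flag = if (length(periods)) "ok" else "no_rotation"),
            class = "rotation_segments")
}

#' Net rotation direction of a walking path
#'
#' Sign of the unwrapped phase progression of `atan2(y - yc, x - xc)`
#' around the path centroid: `+1` counter-clockwise, `-1` clockwise, `0`
#' if the net rotation is below one quarter turn.
#'
#' @param traj data.frame with columns `t`, `x`, `y`.
#' @param center Optional rotation center; default the path centroid.
#' @return `-1`, `0` or `+1`.
#' @export
rotation_direction <- function(traj, center = NULL) {
  if (is.null(center)) center <- c(mean(traj$x), mean(traj$y))
  theta <- unwrap_phase(atan2(traj$y - center[2], traj$x - center[1]))
  net <- theta[length(theta)] - theta[1]
  if (abs(net) < pi / 2) 0 else sign(net)
}

#' Optomotor response from rotation periods
#'
#' `R = direction_sign * 360 / mean(periods)` in deg/s: the animal's mean
#' turning velocity over full rotations, signed positive when the animal
#' circles with the pattern and negative when it circles against it.
#'
#' @param segments A [detect_rotation_periods()] result.
#' @param direction_sign `+1` (co-directional with the pattern) or `-1`.
#' @return list with `R_thrips` (deg/s, `NA` when no full rotation was
#'   detected), `mean_period` (s) and `n_periods`.
#' @export
response_from_periods <- function(segments, direction_sign = 1) {
  stopifnot(inherits(segments, "rotation_segments"))
  stop_field(direction_sign %in% c(-1, 1), "direction_sign", "must be +1/-1")
  if (!length(segments$periods)) {
    return(list(R_thrips = NA_real_, mean_period = NA_real_, n_periods = 0L))
  }
  mp <- mean(segments$periods)
  list(R_thrips = direction_sign * 360 / mp, mean_period = mp,
       n_periods = length(segments$periods))
}

#' Normalize responses within experiment groups
#'
#' Divides every response by the largest response magnitude within its
#' experiment group (one animal's condition series, or whatever grouping
#' the experiment key encodes), preserving sign, so the strongest response
#' in each group maps to magnitude 1.
#'
#' @param responses Numeric vector of signed responses (deg/s).
#' @param experiment Grouping vector (factor-like), same length.
#' @return Numeric vector of normalized responses in `[-1, 1]`; groups
#'   whose responses are all zero or `NA` are returned as `NA` with a
#'   warning (undefined normalization).
#' @export
normalize_responses <- function(responses,
                                experiment = rep(1L, length(responses))) {
  stop_field(length(experiment) == length(responses), "experiment",
             "must match the length of `responses`")
  out <- rep(NA_real_, length(responses))
  for (g in split(seq_along(responses), experiment)) {
    m <- max(abs(responses[g]), na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      warning("undefined normalization: group has no nonzero response")
      next
    }
    out[g] <- responses[g] / m
  }
  out
}

#' Apparent grating wavelength at a given viewing distance
#'
#' A stripe period subtending `wavelength` degrees from the arena center
#' subtends `wavelength * drum_radius / distance` degrees from an animal at
#' `distance` mm from the pattern (arc-length scaling).
#'
#' @param wavelength Nominal wavelength (from the arena center), degrees.
#' @param distance Animal-to-pattern distance, mm.
#' @param drum_radius Pattern drum radius, mm.
#' @return Apparent wavelength, degrees. Vectorized.
#' @examples
#' apparent_wavelength(15, 80)   # ~17.8
#' apparent_wavelength(15, 110)  # ~13.0
#' @export
apparent_wavelength <- function(wavelength, distance, drum_radius = 95) {
  stop_field(all(distance > 0), "distance", "must be positive")
  wavelength * drum_radius / distance
}

#' Egocentric stimulus correction for off-center animals
#'
#' Computes the mean per-frame distance of the animal from the arena center
#' and the apparent wavelength bounds at the nearest
#' (`drum_radius - offset`) and farthest (`drum_radius + offset`) pattern
#' distance. The nominal condition remains the analysis default; the
#' deviations are reported for inspection.
#'
#' @param traj data.frame with columns `t`, `x`, `y` (mm, arena-centered).
#' @param condition A [stimulus_condition()].
#' @param arena An [arena_geometry()].
#' @return list: `mean_distance_from_center` (mm), `lambda_nominal`,
#'   `lambda_apparent_near`, `lambda_apparent_far` (degrees).
#' @export
egocentric_correction <- function(traj, condition, arena = arena_geometry()) {
  offset <- mean(sqrt(traj$x^2 + traj$y^2))
  list(mean_distance_from_center = offset,
       lambda_nominal = condition$wavelength,
       lambda_apparent_near = apparent_wavelength(
         condition$wavelength, arena$drum_radius - offset, arena$drum_radius),
       lambda_apparent_far = apparent_wavelength(
         condition$wavelength, arena$drum_radius + offset, arena$drum_radius))
}

#' Drum speed from a tracked pattern marker
#'
#' The pattern drum speed is calibrated from the number of video frames a
#' tracked marker needs to complete `n_rotations` full turns:
#' `speed = n_rotations * 360 / (frames / frame_rate)`.
#'
#' @param marker_angles Per-frame marker angle, degrees (wrapped or not).
#' @param n_rotations Number of full rotations to time (default 10).
#' @param frame_rate Calibration video frame rate, Hz (default 120).
#' @return Drum speed, deg/s (unsigned).
#' @export
pattern_speed_from_marker <- function(marker_angles, n_rotations = 10,
                                      frame_rate = 120) {
  stop_field(n_rotations >= 1, "n_rotations", "must be >= 1")
  theta <- rad2deg(unwrap_phase(deg2rad(marker_angles)))
  progress <- abs(theta - theta[1])
  idx <- which(progress >= n_rotations * 360)
  if (!length(idx)) {
    stop(sprintf("marker trace covers only %.2f rotations (need %d)",
                 max(progress) / 360, n_rotations))
  }
  frames <- idx[1] - 1L
  n_rotations * 360 / (frames / frame_rate)
}

#' Onset latency of circling after drum start
#'
#' The path heading is estimated from the displacement over a stride of
#' `smoothing_window` seconds (robust to frame-to-frame tracking jitter,
#' whose per-frame displacement can exceed the true step length); the
#' turning rate is the heading change across one stride divided by the
#' stride duration, centered on the stride. The latency is the first time
#' at or after `drum_start` at which the turning rate stays above
#' `turn_threshold` for at least `sustain` seconds.
#'
#' @param traj data.frame with columns `t`, `x`, `y`.
#' @param drum_start Drum rotation onset time, s.
#' @param turn_threshold Sustained turning rate marking circling, deg/s.
#' @param sustain Minimum duration above threshold, s.
#' @param smoothing_window Heading-estimation stride, s.
#' @return Latency in seconds (time above `drum_start`), or `NA_real_` if
#'   the animal never circles.
#' @export
onset_latency <- function(traj, drum_start = 0, turn_threshold = 45,
                          sustain = 0.5, smoothing_window = 0.25) {
  stop_field(drum_start >= traj$t[1] && drum_start <= traj$t[nrow(traj)],
             "drum_start", "must lie within the recording")
  fr <- traj_frame_rate(traj)
  stride <- max(1L, round(smoothing_window * fr))
  n <- nrow(traj)
  if (n <= 2L * stride) return(NA_real_)
  xs <- moving_average(traj$x, stride)
  ys <- moving_average(traj$y, stride)
  i <- seq_len(n - stride)
  heading <- atan2(ys[i + stride] - ys[i], xs[i + stride] - xs[i])
  j <- seq_len(length(heading) - stride)
  dh <- heading[j + stride] - heading[j]
  dh <- dh - 2 * pi * round(dh / (2 * pi))
  span <- traj$t[j + 2L * stride] - traj$t[j]
  rate <- abs(rad2deg(dh)) / (span / 2)
  tt <- traj$t[j + stride]  # rate centered on the middle of the two strides
  ok <- rate >= turn_threshold & tt >= drum_start
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  eligible_first <- which(tt >= drum_start)[1]
  for (k in which(runs$values)) {
    if (tt[ends[k]] - tt[starts[k]] >= sustain) {
      k0 <- starts[k]
      # Circling already under way at the first usable sample: the onset
      # cannot be resolved earlier, report zero latency.
      if (!is.na(eligible_first) && k0 == eligible_first) return(0)
      # The threshold crossing is blurred by the stride windows; refine it
      # with a two-mean least-squares changepoint on a fine-stride rate
      # series around the crossing (the split of a symmetrically blurred
      # step sits at the transition midpoint, i.e. the true onset).
      onset_est <- refine_onset(traj, tt[k0], fr)
      return(max(0, onset_est - drum_start))
    }
  }
  NA_real_
}

# Two-mean changepoint refinement of a circling onset near `t_rough`.
refine_onset <- function(traj, t_rough, fr, halfspan = 3) {
  stride <- max(1L, round(0.05 * fr))
  xs <- moving_average(traj$x, stride)
  ys <- moving_average(traj$y, stride)
  n <- nrow(traj)
  if (n <= 2L * stride) return(t_rough)
  i <- seq_len(n - stride)
  heading <- atan2(ys[i + stride] - ys[i], xs[i + stride] - xs[i])
  j <- seq_len(length(heading) - stride)
  dh <- heading[j + stride] - heading[j]
  dh <- dh - 2 * pi * round(dh / (2 * pi))
  rate <- abs(rad2deg(dh)) / ((traj$t[j + 2L * stride] - traj$t[j]) / 2)
  tt <- traj$t[j + stride]
  win <- which(tt >= t_rough - halfspan & tt <= t_rough + halfspan)
  if (length(win) < 4L) return(t_rough)
  r <- rate[win]
  m <- length(r)
  cs <- cumsum(r)
  cs2 <- cumsum(r^2)
  best_k <- NA_integer_
  best_cost <- Inf
  for (k in seq_len(m - 1L)) {
    n1 <- k; n2 <- m - k
    s1 <- cs[k]; s2 <- cs[m] - cs[k]
    cost <- (cs2[k] - s1^2 / n1) + (cs2[m] - cs2[k] - s2^2 / n2)
    if (cost < best_cost) {
      best_cost <- cost
      best_k <- k
    }
  }
  tt[win[best_k + 1L]]
}

#' Assemble a tuning curve from scored responses
#'
#' Per stimulus condition (wavelength, velocity): mean, SD and N of the
#' normalized responses, with the temporal frequency `f = velocity /
#' wavelength` carried alongside for frequency-domain plots.
#'
#' @param responses data.frame with columns `wavelength`, `velocity`, and
#'   `normalized` (one row per scored trajectory).
#' @return data.frame of class `tuning_curve` with columns `wavelength`,
#'   `velocity`, `temporal_frequency`, `mean`, `sd`, `n`.
#' @export
assemble_tuning_curve <- function(responses) {
  need <- c("wavelength", "velocity", "normalized")
  stop_field(all(need %in% names(responses)), "responses",
             paste("must contain columns", paste(need, collapse = ", ")))
  key <- interaction(responses$wavelength, responses$velocity, drop = TRUE)
  rows <- lapply(split(responses, key), function(d) {
    v <- d$normalized[is.finite(d$normalized)]
    data.frame(wavelength = d$wavelength[1], velocity = d$velocity[1],
               temporal_frequency = d$velocity[1] / d$wavelength[1],
               mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$wavelength, out$velocity), ]
  rownames(out) <- NULL
  class(out) <- c("tuning_curve", "data.frame")
  out
}

#' Score one trajectory end to end
#'
#' Convenience wrapper: exclusion filters, rotation-period detection,
#' signed response, onset latency and egocentric correction for a single
#' trajectory under a known stimulus.
#'
#' @param traj data.frame with columns `t`, `x`, `y`.
#' @param condition A [stimulus_condition()].
#' @param arena An [arena_geometry()].
#' @param drum_start Drum onset time, s.
#' @param ... Passed to [apply_exclusion_filters()] and
#'   [detect_rotation_periods()] (matched by name).
#' @return One-row data.frame: `wavelength`, `velocity`, `R_thrips`,
#'   `n_periods`, `onset_latency`, `mean_distance_from_center`, `excluded`,
#'   `exclusion_reasons`.
#' @export
score_trajectory <- function(traj, condition, arena = arena_geometry(),
                             drum_start = 0, ...) {
  dots <- list(...)
  pick <- function(f) dots[names(dots) %in% names(formals(f))]
  traj <- do.call(apply_exclusion_filters,
                  c(list(traj = traj, arena = arena),
                    pick(apply_exclusion_filters)))
  excluded <- attr(traj, "excluded")
  reasons <- paste(attr(traj, "exclusion_reasons"), collapse = ";")
  ego <- egocentric_correction(traj, condition, arena)
  if (excluded) {
    return(data.frame(wavelength = condition$wavelength,
                      velocity = condition$velocity,
                      R_thrips = NA_real_, n_periods = 0L,
                      onset_latency = NA_real_,
                      mean_distance_from_center =
                        ego$mean_distance_from_center,
                      excluded = TRUE, exclusion_reasons = reasons))
  }
  seg <- do.call(detect_rotation_periods,
                 c(list(traj = traj), pick(detect_rotation_periods)))
  dir_animal <- rotation_direction(traj)
  sign_co <- if (dir_animal == 0) 1 else dir_animal * condition$direction
  resp <- response_from_periods(seg, if (sign_co >= 0) 1 else -1)
  lat <- onset_latency(traj, drum_start)
  data.frame(wavelength = condition$wavelength,
             velocity = condition$velocity,
             R_thrips = resp$R_thrips, n_periods = resp$n_periods,
             onset_latency = lat,
             mean_distance_from_center = ego$mean_distance_from_center,
             excluded = FALSE, exclusion_reasons = reasons)
}
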