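#' Specification for a synthetic walking trajectory
#'
#' Defaults emulate the behavioral assay: 68 s recordings at 60 frames/s in
#' a 15 mm radius container, with a circling onset latency of 1.76 s (SD
#' 1.0 s) after drum start.
#'
#' @param turning_velocity Ground-truth circling velocity, deg/s, signed
#'   (positive = counter-clockwise).
#' @param path_radius Radius of the circular path, mm.
#' @param onset_latency_mean,onset_latency_sd Latency between drum start
#'   (t = 0 unless a wall-following span precedes it) and circling onset, s.
#' @param duration Recording duration, s.
#' @param frame_rate Sampling rate, Hz.
#' @param position_noise_sd Isotropic Gaussian position noise, mm.
#' @param rest_fraction Fraction of the duration, at the end, spent
#'   resting (speed ~ 0); in `[0, 1)`.
#' @param wall_follow_span Initial span glued to the container wall, s
#'   (0 = none).
#' @param container_radius Walking container radius, mm.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_walk_spec`.
#' @export
synthetic_walk_spec <- function(turning_velocity, path_radius = 5,
                                onset_latency_mean = 1.76,
                                onset_latency_sd = 1.0,
                                duration = 68, frame_rate = 60,
                                position_noise_sd = 0,
                                rest_fraction = 0, wall_follow_span = 0,
                                container_radius = 15, seed = 1) {
  stop_field(duration > 0, "duration", "must be positive")
  stop_field(frame_rate > 0, "frame_rate", "must be positive")
  stop_field(rest_fraction >= 0 && rest_fraction < 1,
             "rest_fraction", "must lie in [0, 1)")
  stop_field(wall_follow_span >= 0, "wall_follow_span", "must be >= 0")
  if (wall_follow_span > duration) {
    stop("invalid `wall_follow_span`: exceeds the recording duration",
         call. = FALSE)
  }
  stop_field(abs(path_radius) + 3 * position_noise_sd < container_radius,
             "path_radius",
             "path radius plus noise must fit inside the container")
  structure(list(turning_velocity = turning_velocity,
                 path_radius = abs(path_radius),
                 onset_latency_mean = onset_latency_mean,
                 onset_latency_sd = onset_latency_sd,
                 duration = duration, frame_rate = frame_rate,
                 position_noise_sd = position_noise_sd,
                 rest_fraction = rest_fraction,
                 wall_follow_span = wall_follow_span,
                 container_radius = container_radius, seed = seed),
            class = "synthetic_walk_spec")
}

#' Generate a synthetic walking trajectory
#'
#' Builds a trajectory with the phases the scoring pipeline must handle:
#' an optional initial wall-following span glued to the container
#' circumference, a low-curvature random walk until the circling onset
#' (wall span plus a latency drawn from the configured normal
#' distribution, truncated to be non-negative), continuous circling at the
#' signed ground-truth turning velocity on the configured path radius, and
#' an optional terminal rest bout occupying `rest_fraction` of the
#' duration. Isotropic Gaussian position noise is added last.
#'
#' @param spec A [synthetic_walk_spec()].
#' @return data.frame of class `walk_trajectory` with columns `t`, `x`,
#'   `y` and attribute `truth` (list: `turning_velocity`, `onset_time`,
#'   `latency`, `path_radius`, `circle_center`, `rest_start`).
#' @export
generate_walk_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_walk_spec"))
  with_seed(spec$seed, {
    fr <- spec$frame_rate
    n <- round(spec$duration * fr)
    t <- (seq_len(n) - 1) / fr
    dt <- 1 / fr
    x <- numeric(n)
    y <- numeric(n)

    latency <- if (spec$onset_latency_sd > 0 || spec$onset_latency_mean > 0) {
      max(0, stats::rnorm(1, spec$onset_latency_mean, spec$onset_latency_sd))
    } else {
      0
    }
    onset <- min(spec$wall_follow_span + latency, spec$duration)
    rest_start <- spec$duration * (1 - spec$rest_fraction)

    # phase 1: wall following (exactly on the container circumference)
    i_wall <- which(t < spec$wall_follow_span)
    if (length(i_wall)) {
      ang0 <- stats::runif(1, 0, 2 * pi)
      wall_speed <- 4 / spec$container_radius  # rad/s, ~4 mm/s tangential
      ang <- ang0 + wall_speed * t[i_wall]
      x[i_wall] <- spec$container_radius * cos(ang)
      y[i_wall] <- spec$container_radius * sin(ang)
    }

    # phase 2: low-curvature random walk until circling onset
    i_pre <- which(t >= spec$wall_follow_span & t < onset)
    pos <- if (length(i_wall)) {
      0.9 * c(x[max(i_wall)], y[max(i_wall)])
    } else {
      stats::runif(2, -spec$container_radius / 4, spec$container_radius / 4)
    }
    heading <- stats::runif(1, 0, 2 * pi)
    walk_speed <- 3  # mm/s
    bound <- 0.8 * spec$container_radius
    for (i in i_pre) {
      x[i] <- pos[1]
      y[i] <- pos[2]
      heading <- heading + stats::rnorm(1, 0, deg2rad(10) * sqrt(dt))
      step <- walk_speed * dt * c(cos(heading), sin(heading))
      cand <- pos + step
      if (vnorm(cand) > bound) {
        heading <- atan2(-pos[2], -pos[1]) + stats::rnorm(1, 0, 0.3)
        cand <- pos + walk_speed * dt * c(cos(heading), sin(heading))
      }
      pos <- cand
    }

    # phase 3: circling at the ground-truth turning velocity
    i_circ <- which(t >= onset)
    center <- c(0, 0)
    phi0 <- stats::runif(1, 0, 2 * pi)
    if (length(i_circ)) {
      entry <- if (length(i_pre) || length(i_wall)) pos else c(0, 0)
      max_center <- spec$container_radius - spec$path_radius -
        3 * spec$position_noise_sd - 1e-9
      max_center <- max(0, max_center)
      dir_entry <- if (vnorm(entry) > 1e-9) {
        unitize(c(entry, 0))[1:2]
      } else {
        c(cos(phi0), sin(phi0))
      }
      # circle through the entry point (no position jump at onset),
      # pulled toward the arena center if it would leave the container
      center <- entry - spec$path_radius * dir_entry
      if (vnorm(center) > max_center) {
        center <- center * max_center / vnorm(center)
      }
      phi0 <- atan2(entry[2] - center[2], entry[1] - center[1])
      omega <- deg2rad(spec$turning_velocity)
      phi <- phi0 + omega * (t[i_circ] - onset)
      x[i_circ] <- center[1] + spec$path_radius * cos(phi)
      y[i_circ] <- center[2] + spec$path_radius * sin(phi)
    }

    # phase 4: terminal rest bout (freeze position)
    i_rest <- which(t >= rest_start)
    if (length(i_rest) && i_rest[1] > 1) {
      x[i_rest] <- x[i_rest[1] - 1]
      y[i_rest] <- y[i_rest[1] - 1]
    }

    if (spec$position_noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, spec$position_noise_sd)
      y <- y + stats::rnorm(n, 0, spec$position_noise_sd)
    }

    out <- data.frame(t = t, x = x, y = y)
    attr(out, "truth") <- list(turning_velocity = spec$turning_velocity,
                               onset_time = onset, latency = latency,
                               path_radius = spec$path_radius,
                               circle_center = center,
                               rest_start = rest_start)
    class(out) <- c("walk_trajectory", "data.frame")
    out
  })
}
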