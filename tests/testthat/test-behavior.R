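test_that("arena defaults reproduce the assay geometry", {
  arena <- arena_geometry()
  expect_equal(arena$drum_circumference, 0.597, tolerance = 1e-3)
  expect_equal(arena$min_pattern_distance, 80)
  expect_equal(arena$max_pattern_distance, 110)
  expect_error(arena_geometry(drum_radius = 10), "radii")
})

test_that("stimulus conditions derive the temporal frequency", {
  cond <- stimulus_condition(60, 210)
  expect_equal(cond$temporal_frequency, 3.5)
  expect_equal(stimulus_condition(60, -210)$direction, -1)
  expect_error(stimulus_condition(-5, 100), "wavelength")
})

test_that("exclusion filters flag wall-following and short walks", {
  wall <- generate_walk_trajectory(synthetic_walk_spec(
    120, wall_follow_span = 5, onset_latency_mean = 0, onset_latency_sd = 0,
    position_noise_sd = 0.1, seed = 1))
  fw <- apply_exclusion_filters(wall)
  expect_true(attr(fw, "excluded"))
  expect_true("wall_following" %in% attr(fw, "exclusion_reasons"))

  # circling for 8 s then resting: under the 10 s walk-time rule
  short <- generate_walk_trajectory(synthetic_walk_spec(
    120, onset_latency_mean = 0, onset_latency_sd = 0,
    rest_fraction = 60 / 68, seed = 2))
  fs <- apply_exclusion_filters(short)
  expect_true(attr(fs, "excluded"))
  expect_true("short_walk" %in% attr(fs, "exclusion_reasons"))

  good <- generate_walk_trajectory(synthetic_walk_spec(
    120, onset_latency_mean = 0, onset_latency_sd = 0, seed = 3))
  expect_false(attr(apply_exclusion_filters(good), "excluded"))
  expect_lt(max(sqrt(good$x^2 + good$y^2)), 10 + 1e-9)
})

test_that("both exclusion rules are always evaluated (order-free flags)", {
  # wall-following for 5 s, then resting: trips both rules at once
  both <- generate_walk_trajectory(synthetic_walk_spec(
    120, wall_follow_span = 5, onset_latency_mean = 0, onset_latency_sd = 0,
    rest_fraction = 60 / 68, position_noise_sd = 0.1, seed = 4))
  fb <- apply_exclusion_filters(both)
  expect_setequal(attr(fb, "exclusion_reasons"),
                  c("wall_following", "short_walk"))
})

test_that("rotation periods follow circular kinematics", {
  w90 <- generate_walk_trajectory(synthetic_walk_spec(
    90, onset_latency_mean = 0, onset_latency_sd = 0, seed = 2))
  seg <- detect_rotation_periods(w90)
  expect_equal(unique(round(seg$periods, 9)), 4.0)
  w360 <- generate_walk_trajectory(synthetic_walk_spec(
    360, onset_latency_mean = 0, onset_latency_sd = 0, seed = 2))
  seg360 <- detect_rotation_periods(w360)
  expect_true(all(abs(seg360$periods - 1.0) <= 1 / 60 + 1e-12))
  # fewer than two peaks: flagged, not an error
  flat <- data.frame(t = (0:599) / 60, x = (0:599) / 600, y = 0)
  expect_equal(detect_rotation_periods(flat)$flag, "no_rotation")
})

test_that("period detection matches the brute-force local-maximum oracle", {
  for (s in c(7, 12, 30)) {
    w <- generate_walk_trajectory(synthetic_walk_spec(
      120, position_noise_sd = 0.2, onset_latency_mean = 0,
      onset_latency_sd = 0, seed = s))
    seg <- detect_rotation_periods(w, smoothing_window = 0.25,
                                   min_prominence = 1)
    width <- round(0.25 * 60)
    ysm <- oracle_smooth(w$y, width)
    oracle <- brute_force_peaks(ysm, min_prominence = 1)
    expect_equal(w$t[oracle], seg$peak_times)
    expect_equal(mean(seg$periods), 2 * pi / (120 * pi / 180) / 1,
                 tolerance = 0.05 * 3)
  }
})

test_that("responses follow the 360/period rule with the sign convention", {
  seg <- structure(list(peak_times = c(0, 2, 4), periods = c(2, 2),
                        flag = "ok"), class = "rotation_segments")
  expect_equal(response_from_periods(seg, 1)$R_thrips, 180)
  seg1 <- structure(list(peak_times = c(0, 1), periods = 1, flag = "ok"),
                    class = "rotation_segments")
  expect_equal(response_from_periods(seg1, -1)$R_thrips, -360)
  empty <- structure(list(peak_times = numeric(0), periods = numeric(0),
                          flag = "no_rotation"), class = "rotation_segments")
  expect_true(is.na(response_from_periods(empty, 1)$R_thrips))

  w <- generate_walk_trajectory(synthetic_walk_spec(
    120, position_noise_sd = 0.2, seed = 7))
  sc <- score_trajectory(w, stimulus_condition(60, 420))
  expect_lt(abs(sc$R_thrips - 120) / 120, 0.05)

  # circling against the pattern scores negative
  wn <- generate_walk_trajectory(synthetic_walk_spec(
    -180, onset_latency_mean = 0, onset_latency_sd = 0, seed = 5))
  sn <- score_trajectory(wn, stimulus_condition(60, 420))
  expect_equal(sn$R_thrips, -180, tolerance = 0.05 * 180)
})

test_that("per-experiment normalization preserves sign and argmax", {
  expect_equal(normalize_responses(c(90, 180, -45)), c(0.5, 1, -0.25))
  expect_equal(normalize_responses(135), 1)
  set.seed(9)
  r <- rnorm(12, 100, 60)
  n1 <- normalize_responses(r)
  expect_equal(which.max(abs(n1)), which.max(abs(r)))
  expect_equal(sign(n1), sign(r))
  expect_equal(normalize_responses(n1), n1)  # idempotent
  expect_warning(normalize_responses(c(0, 0)), "undefined")
  # grouping is respected
  n2 <- normalize_responses(c(10, 20, 1, 4), c("a", "a", "b", "b"))
  expect_equal(n2, c(0.5, 1, 0.25, 1))
})

test_that("egocentric correction reproduces the apparent-wavelength endpoints", {
  expect_equal(apparent_wavelength(15, 80), 17.8, tolerance = 0.05)
  expect_equal(apparent_wavelength(15, 110), 13.0, tolerance = 0.05)
  expect_equal(apparent_wavelength(45, 95), 45)  # animal at the center
  tt <- (0:599) / 60
  circ <- data.frame(t = tt, x = 6 * cos(pi * tt), y = 6 * sin(pi * tt))
  ego <- egocentric_correction(circ, stimulus_condition(15, 100))
  expect_equal(ego$mean_distance_from_center, 6, tolerance = 1e-9)
  expect_gt(ego$lambda_apparent_near, 15)
  expect_lt(ego$lambda_apparent_far, 15)
})

test_that("drum speed calibration inverts frame counting", {
  ang <- (0:1200 * 3) %% 360  # 3 deg/frame at 120 Hz = 360 deg/s
  expect_equal(pattern_speed_from_marker(ang), 360)
  ang2 <- (0:2400 * 1.5) %% 360
  expect_equal(pattern_speed_from_marker(ang2), 180)
  ang3 <- cumsum(c(0, rep(296 / 120, 2000))) %% 360
  speed <- pattern_speed_from_marker(ang3)
  # one-frame quantization bound on the recovered speed
  frames <- 3600 / (296 / 120)
  quant <- 3600 / (floor(frames) / 120) - 3600 / ((floor(frames) + 1) / 120)
  expect_lte(abs(speed - 296), quant + 1e-9)
  expect_error(pattern_speed_from_marker((0:100) %% 360, 10), "rotations")
})

test_that("onset latency locates the circling changepoint", {
  w <- generate_walk_trajectory(synthetic_walk_spec(
    120, onset_latency_mean = 1.76, onset_latency_sd = 0,
    position_noise_sd = 0.1, seed = 6))
  expect_lt(abs(onset_latency(w) - 1.76), 0.25)
  w0 <- generate_walk_trajectory(synthetic_walk_spec(
    90, onset_latency_mean = 0, onset_latency_sd = 0, seed = 2))
  expect_equal(onset_latency(w0), 0)
  never <- generate_walk_trajectory(synthetic_walk_spec(
    120, onset_latency_mean = 100, onset_latency_sd = 0, duration = 20,
    position_noise_sd = 0.1, seed = 4))
  expect_true(is.na(onset_latency(never)))
})

test_that("tuning curves aggregate condition-wise means and SDs", {
  one <- data.frame(wavelength = c(60, 60), velocity = c(120, 240),
                    normalized = c(0.4, 0.9))
  tc <- assemble_tuning_curve(one)
  expect_equal(tc$sd, c(0, 0))
  expect_equal(tc$temporal_frequency, c(2, 4))
  rep5 <- data.frame(wavelength = 60, velocity = 120,
                     normalized = rep(0.7, 5))
  tc5 <- assemble_tuning_curve(rep5)
  expect_equal(tc5$mean, 0.7)
  expect_equal(tc5$sd, 0)
  expect_equal(tc5$n, 5)

  # synthetic dataset: condition means sit within 2 SE of the model truth
  spec <- synthetic_tuning_spec(tau_true = 0.041, noise_sd = 0.05,
                                n_replicates = 20, seed = 11)
  d <- generate_tuning_dataset(spec)
  tc_d <- tuning_means(d)
  p <- emd_params(0.041, 17.8, 17.7)
  truth <- emd_response(p, tc_d$wavelength, tc_d$velocity)
  truth <- truth / max(abs(truth))
  se <- tc_d$sd / sqrt(tc_d$n)
  expect_true(all(abs(tc_d$mean - truth) <= 2 * se + 0.02))
})

test_that("trajectory and stimulus files round trip", {
  w <- generate_walk_trajectory(synthetic_walk_spec(90, seed = 2))
  tp <- tempfile(fileext = ".tsv")
  write_trajectory(w, tp)
  back <- read_trajectory(tp)
  expect_equal(back$y, w$y, tolerance = 1e-9)
  sp <- tempfile(fileext = ".txt")
  write_sidecar(list(lambda_deg = 60, velocity_deg_s = 210), sp)
  cond <- read_stimulus(sp)
  expect_equal(cond$temporal_frequency, 3.5)
})
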