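test_that("generator specifications validate their fields by name", {
  expect_error(synthetic_eye_spec(n_ommatidia = 2), "n_ommatidia")
  expect_error(synthetic_eye_spec(target_io_angle = 95), "target_io_angle")
  expect_error(synthetic_eye_spec(lens_diameter_mean = -1),
               "lens_diameter_mean")
  expect_error(synthetic_walk_spec(90, duration = -1), "duration")
  expect_error(synthetic_walk_spec(90, wall_follow_span = 100),
               "wall_follow_span")
  expect_error(synthetic_walk_spec(90, path_radius = 20), "path_radius")
  expect_error(synthetic_tuning_spec(tau_true = 0), "tau_true")
  expect_error(synthetic_tuning_spec(wavelengths = numeric(0)),
               "wavelengths")
})

test_that("fixed seeds reproduce every emitted number bit for bit", {
  e1 <- generate_synthetic_eye(synthetic_eye_spec(20, seed = 5))
  e2 <- generate_synthetic_eye(synthetic_eye_spec(20, seed = 5))
  expect_identical(e1$markers, e2$markers)
  expect_identical(e1$truth$axes, e2$truth$axes)
  e3 <- generate_synthetic_eye(synthetic_eye_spec(20, seed = 6))
  expect_false(identical(e1$markers$x, e3$markers$x))

  w1 <- generate_walk_trajectory(synthetic_walk_spec(120, seed = 5,
                                                     position_noise_sd = 0.1))
  w2 <- generate_walk_trajectory(synthetic_walk_spec(120, seed = 5,
                                                     position_noise_sd = 0.1))
  expect_identical(w1$x, w2$x)

  d1 <- generate_tuning_dataset(synthetic_tuning_spec(seed = 5))
  d2 <- generate_tuning_dataset(synthetic_tuning_spec(seed = 5))
  expect_identical(d1$response, d2$response)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(generate_synthetic_eye(synthetic_eye_spec(5, seed = 99)))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("noiseless eye construction is exact for explicit axes", {
  a <- 17.8 * pi / 180
  tbl <- synthetic_eye_from_axes(rbind(c(1, 0, 0), c(cos(a), sin(a), 0)),
                                 diameters = 8.76)
  model <- reconstruct_eye(tbl)
  expect_equal(model$edges$io_angle, 17.8, tolerance = 1e-9)
  expect_equal(model$geometry$lens_diameter, c(8.76, 8.76),
               tolerance = 1e-12)
})

test_that("noisy synthetic eyes recover the target mean angle within 1 degree", {
  eye <- generate_synthetic_eye(synthetic_eye_spec(
    n_ommatidia = 60, target_io_angle = 17.8, io_angle_sd = 4.4,
    marker_noise_sd = 0.1, seed = 1))
  expect_equal(eye$truth$io_mean, 17.8, tolerance = 0.05)
  model <- reconstruct_eye(eye$markers, axis_method = "normal")
  io <- interommatidial_angles(model)
  expect_lt(abs(io$summary$mean - 17.8), 1)
})

test_that("walk trajectories respect the container except when wall-following", {
  w <- generate_walk_trajectory(synthetic_walk_spec(120, seed = 3,
                                                    position_noise_sd = 0.1))
  expect_true(all(sqrt(w$x^2 + w$y^2) <= 15 + 1e-9))
  ww <- generate_walk_trajectory(synthetic_walk_spec(
    120, wall_follow_span = 5, position_noise_sd = 0, seed = 3))
  on_wall <- abs(sqrt(ww$x^2 + ww$y^2) - 15) < 1e-9
  expect_true(all(on_wall[ww$t < 5]))
  expect_true(all(sqrt(ww$x^2 + ww$y^2)[ww$t >= 5] <= 15 + 1e-9))
})

test_that("walk kinematics carry the configured ground truth", {
  w <- generate_walk_trajectory(synthetic_walk_spec(
    90, onset_latency_mean = 0, onset_latency_sd = 0, seed = 2))
  seg <- detect_rotation_periods(w)
  expect_equal(mean(seg$periods), 4.0, tolerance = 1 / 60)
  wn <- generate_walk_trajectory(synthetic_walk_spec(
    -180, onset_latency_mean = 0, onset_latency_sd = 0, seed = 2))
  expect_equal(rotation_direction(wn), -1)
  tr <- attr(wn, "truth")
  expect_equal(tr$turning_velocity, -180)
})

test_that("rest bouts freeze the trajectory tail", {
  w <- generate_walk_trajectory(synthetic_walk_spec(
    120, rest_fraction = 0.25, onset_latency_mean = 0, onset_latency_sd = 0,
    position_noise_sd = 0, seed = 8))
  tail_idx <- w$t >= 68 * 0.75
  expect_lt(max(abs(diff(w$x[tail_idx]))), 1e-12)
})

test_that("tuning datasets are renormalized per replicate and carry truth", {
  spec <- synthetic_tuning_spec(tau_true = 0.041, noise_sd = 0.05,
                                n_replicates = 10, seed = 2)
  d <- generate_tuning_dataset(spec)
  for (r in split(d, d$replicate)) {
    expect_equal(max(abs(r$response)), 1, tolerance = 1e-12)
  }
  expect_equal(attr(d, "truth")$tau_true, 0.041)
  # zero velocity gives exactly zero response (odd symmetry)
  d0 <- generate_tuning_dataset(synthetic_tuning_spec(
    velocities = c(0, 100), noise_sd = 0, n_replicates = 1))
  expect_equal(d0$response[d0$velocity == 0], 0)
})
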