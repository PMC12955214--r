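test_that("head normalization is the identity for a canonical ocelli pose", {
  oc <- rbind(c(20, 0, 0), c(-10, 10 * sqrt(3), 0), c(-10, -10 * sqrt(3), 0))
  nh <- normalize_head(oc)
  expect_equal(nh$frame$rotation, diag(3), tolerance = 1e-12)
  expect_equal(nh$frame$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(det(nh$frame$rotation), 1, tolerance = 1e-12)
})

test_that("head normalization inverts an applied rigid motion", {
  set.seed(11)
  eye <- generate_synthetic_eye(synthetic_eye_spec(n_ommatidia = 12,
                                                   io_angle_sd = 0))
  for (i in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, 0, 50)
    moved <- transform_markers(eye$markers, R, shift)
    oc <- as.matrix(moved[grepl("^ocellus", moved$marker_role),
                          c("x", "y", "z")])
    nh <- normalize_head(oc, moved)
    # markers were canonical before the motion, so normalization restores them
    expect_equal(nh$markers$x, eye$markers$x, tolerance = 1e-8)
    expect_equal(nh$markers$y, eye$markers$y, tolerance = 1e-8)
    expect_equal(nh$markers$z, eye$markers$z, tolerance = 1e-8)
    expect_equal(nh$frame$rotation %*% R, diag(3), tolerance = 1e-8)
  }
})

test_that("collinear ocelli raise a degenerate-frame error", {
  oc <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(normalize_head(oc), "collinear")
})

test_that("circle fit recovers an exact lens base in any pose", {
  phi <- seq(0, 300, by = 60) * pi / 180
  base <- cbind(4.38 * cos(phi), 4.38 * sin(phi), 0)
  fit <- fit_lens_circle(base, outer_tip = c(0, 0, 2))
  expect_equal(fit$diameter, 8.76, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_equal(fit$normal, c(0, 0, 1), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    R <- random_rotation()
    shift <- rnorm(3, 0, 100)
    fit2 <- fit_lens_circle(base %*% t(R) + rep(1, 6) %o% shift)
    expect_equal(fit2$diameter, 8.76, tolerance = 1e-9)
  }
  line <- cbind(1:6, 2 * (1:6), 3 * (1:6))
  expect_error(fit_lens_circle(line), "collinear")
})

test_that("circle fit under 0.1 um marker noise stays within 0.15 um", {
  phi <- seq(0, 300, by = 60) * pi / 180
  base <- cbind(4.38 * cos(phi), 4.38 * sin(phi), 0)
  set.seed(100)
  errs <- replicate(100, {
    noisy <- base + matrix(rnorm(18, 0, 0.1), 6, 3)
    abs(fit_lens_circle(noisy)$diameter - 8.76)
  })
  expect_lt(mean(errs), 0.15)
})

test_that("visual-axis constructions agree on a symmetric dome and track a
           constructed offset", {
  tbl <- synthetic_eye_from_axes(matrix(c(0, 0, 1), 1), diameters = 8.76,
                                 ocelli = FALSE)
  lens <- marker_sets_from_table(tbl)$lenses[[1]]
  circ <- fit_lens_circle(lens$base_points, lens$outer_tip)
  a_top <- compute_visual_axis(lens, circ, "top")
  a_norm <- compute_visual_axis(lens, circ, "normal")
  expect_equal(a_top, a_norm, tolerance = 1e-12)
  expect_equal(a_top, c(0, 0, 1), tolerance = 1e-12)

  # displace the outer tip 10 degrees off the base normal
  h <- 1.61
  lens10 <- lens
  lens10$outer_tip <- circ$center +
    h * c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  t10 <- compute_visual_axis(lens10, circ, "top")
  n10 <- compute_visual_axis(lens10, circ, "normal")
  expect_equal(acos(sum(t10 * n10)) * 180 / pi, 10, tolerance = 1e-9)

  lens0 <- lens
  lens0$outer_tip <- circ$center
  expect_error(compute_visual_axis(lens0, circ), "coincides")
})

test_that("neighbor graphs honor minimal and symmetric cases", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  e <- build_neighbor_graph(tri)
  expect_equal(nrow(e), 3)  # complete triangle
  ring <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  e2 <- build_neighbor_graph(ring, "knn", k = 2)
  deg <- table(factor(c(e2[, 1], e2[, 2]), levels = 1:6))
  expect_true(all(deg == 2))
  expect_true(all(e2[, 1] < e2[, 2]))
  expect_error(build_neighbor_graph(tri[1, , drop = FALSE]), "two")
})

test_that("triangulation of a synthetic eye yields degrees in [3, 9]", {
  for (s in 1:3) {
    eye <- generate_synthetic_eye(synthetic_eye_spec(60, io_angle_sd = 4.4,
                                                     seed = s))
    e <- build_neighbor_graph(eye$truth$centers)
    deg <- table(factor(c(e[, 1], e[, 2]), levels = 1:60))
    expect_true(all(deg >= 3 & deg <= 9))
  }
})

test_that("interommatidial angles match constructed pairs", {
  a <- 17.8 * pi / 180
  axes <- rbind(c(1, 0, 0), c(cos(a), sin(a), 0))
  tbl <- synthetic_eye_from_axes(axes, diameters = 8.76)
  model <- reconstruct_eye(tbl)
  io <- interommatidial_angles(model)
  expect_equal(io$edges$io_angle, 17.8, tolerance = 1e-9)
  # parallel axes: zero angle
  tbl0 <- synthetic_eye_from_axes(rbind(c(1, 0, 0), c(1, 0, 0)),
                                  diameters = 8.76)
  tbl0$x[tbl0$ommatidium_id == 2 & !is.na(tbl0$ommatidium_id)] <-
    tbl0$x[tbl0$ommatidium_id == 2 & !is.na(tbl0$ommatidium_id)] + 10
  m0 <- reconstruct_eye(tbl0)
  expect_equal(m0$edges$io_angle, 0, tolerance = 1e-9)
})

test_that("noiseless synthetic eyes reconstruct to numerical precision", {
  eye <- generate_synthetic_eye(synthetic_eye_spec(60, io_angle_sd = 0,
                                                   marker_noise_sd = 0))
  model <- reconstruct_eye(eye$markers)
  expect_equal(sort(model$geometry$lens_diameter), sort(eye$truth$diameters),
               tolerance = 1e-9)
  axes <- as.matrix(model$geometry[, c("ax", "ay", "az")])
  expect_lt(max(abs(axes - eye$truth$axes)), 1e-9)
  io <- interommatidial_angles(model)
  expect_equal(io$summary$mean, eye$truth$io_mean, tolerance = 1e-9)
  expect_equal(io$summary$mean, 17.8, tolerance = 1)
})

test_that("derived scalars are invariant under rigid motion of the cloud", {
  eye <- generate_synthetic_eye(synthetic_eye_spec(20, io_angle_sd = 3,
                                                   seed = 4))
  base <- reconstruct_eye(eye$markers, normalize_head_frame = FALSE)
  set.seed(21)
  for (i in 1:3) {
    moved <- transform_markers(eye$markers, random_rotation(),
                               rnorm(3, 0, 200))
    m2 <- reconstruct_eye(moved, normalize_head_frame = FALSE)
    expect_equal(m2$geometry$lens_diameter, base$geometry$lens_diameter,
                 tolerance = 1e-9)
    expect_equal(m2$geometry$h_outer, base$geometry$h_outer,
                 tolerance = 1e-9)
    expect_equal(sort(m2$edges$io_angle), sort(base$edges$io_angle),
                 tolerance = 1e-9)
  }
})

test_that("eye-map projection follows the az/el convention and inverts", {
  axes <- rbind(c(1, 0, 0), c(0, 0, 1))
  tbl <- synthetic_eye_from_axes(axes, diameters = 8.76, eye_radius = 50)
  model <- reconstruct_eye(tbl, normalize_head_frame = FALSE)
  proj <- eye_map_projection(model)
  i_x <- which.min(abs(proj$elevation))
  expect_equal(proj$azimuth[i_x], 0, tolerance = 1e-9)
  expect_equal(proj$elevation[i_x], 0, tolerance = 1e-9)
  expect_equal(max(proj$elevation), 90, tolerance = 1e-6)
  # closed-form round trip away from the poles
  set.seed(3)
  az <- runif(30, -179, 179)
  el <- runif(30, -85, 85)
  v <- axis_from_azel(az, el)
  expect_equal(atan2(v[, 2], v[, 1]) * 180 / pi, az, tolerance = 1e-9)
  expect_equal(asin(v[, 3]) * 180 / pi, el, tolerance = 1e-9)
})

test_that("marker tables survive a write/read round trip", {
  eye <- generate_synthetic_eye(synthetic_eye_spec(5, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_marker_table(eye$markers, path)
  back <- read_marker_table(path)
  expect_equal(back$x, eye$markers$x, tolerance = 1e-9)
  expect_equal(back$marker_role, eye$markers$marker_role)
  m1 <- reconstruct_eye(back)
  m2 <- reconstruct_eye(eye$markers)
  expect_equal(m1$geometry$lens_diameter, m2$geometry$lens_diameter,
               tolerance = 1e-9)
})
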