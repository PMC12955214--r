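#' Specification for a synthetic compound eye
#'
#' Parameters of the synthetic landmark generator. Defaults emulate a
#' miniature-insect eye: ~60 ommatidia, mean interommatidial angle 17.8
#' degrees (SD 4.4), mean lens diameter 8.76 micrometres (SD 0.76), outer /
#' inner lens half thicknesses 1.61 / 1.28 micrometres.
#'
#' @param n_ommatidia Number of ommatidia (>= 3).
#' @param target_io_angle Target mean interommatidial angle, degrees, in
#'   (0, 90).
#' @param io_angle_sd Angular jitter of the axis lattice, degrees.
#' @param lens_diameter_mean,lens_diameter_sd Lens diameter distribution,
#'   micrometres.
#' @param outer_half_thickness,inner_half_thickness Lens tip heights above /
#'   below the lens base plane, micrometres.
#' @param rhabdomere_depth Depth of the rhabdomere tip below the lens
#'   center along the inward axis, micrometres.
#' @param marker_noise_sd Isotropic Gaussian noise added to every marker
#'   coordinate, micrometres.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_eye_spec`.
#' @export
synthetic_eye_spec <- function(n_ommatidia = 60, target_io_angle = 17.8,
                               io_angle_sd = 4.4,
                               lens_diameter_mean = 8.76,
                               lens_diameter_sd = 0.76,
                               outer_half_thickness = 1.61,
                               inner_half_thickness = 1.28,
                               rhabdomere_depth = 15,
                               marker_noise_sd = 0, seed = 1) {
  stop_field(n_ommatidia >= 3, "n_ommatidia", "must be >= 3")
  stop_field(target_io_angle > 0 && target_io_angle < 90,
             "target_io_angle", "must lie in (0, 90) degrees")
  stop_field(io_angle_sd >= 0, "io_angle_sd", "must be >= 0")
  for (f in c("lens_diameter_mean", "outer_half_thickness",
              "inner_half_thickness", "rhabdomere_depth")) {
    stop_field(get(f) > 0, f, "must be positive")
  }
  stop_field(lens_diameter_sd >= 0, "lens_diameter_sd", "must be >= 0")
  stop_field(marker_noise_sd >= 0, "marker_noise_sd", "must be >= 0")
  structure(list(n_ommatidia = as.integer(n_ommatidia),
                 target_io_angle = target_io_angle,
                 io_angle_sd = io_angle_sd,
                 lens_diameter_mean = lens_diameter_mean,
                 lens_diameter_sd = lens_diameter_sd,
                 outer_half_thickness = outer_half_thickness,
                 inner_half_thickness = inner_half_thickness,
                 rhabdomere_depth = rhabdomere_depth,
                 marker_noise_sd = marker_noise_sd,
                 seed = seed),
            class = "synthetic_eye_spec")
}

# Canonical ocelli triangle: centroid at the origin, plane normal +z,
# first ocellus on +x, so head normalization is the identity.
canonical_ocelli <- function(size = 20) {
  rbind(c(size, 0, 0),
        c(-size / 2, size * sqrt(3) / 2, 0),
        c(-size / 2, -size * sqrt(3) / 2, 0))
}

# Mean pairwise angle over the Delaunay neighbor graph of a set of axes.
lattice_io_mean <- function(axes) {
  e <- build_neighbor_graph(axes)
  mean(vapply(seq_len(nrow(e)), function(r) {
    angle_between_deg(axes[e[r, 1], ], axes[e[r, 2], ])
  }, numeric(1)))
}

# Hexagonal lattice of unit directions on a spherical cap centered on +x:
# rows of constant polar angle spaced sqrt(3)/2 * spacing apart, points
# spaced `spacing` along each row, alternate rows offset by half a step.
# The realized lattice (one fixed jitter draw) is rescaled about the cap
# center so that the mean neighbor angle hits `spacing_deg` exactly:
# jitter both spreads the pairwise angles and inflates their mean, so an
# uncalibrated lattice would sit above target.
cap_lattice_axes <- function(n, spacing_deg, jitter_deg = 0) {
  axes <- cap_lattice_raw(n, spacing_deg, jitter_deg)
  if (n < 4) return(axes)
  scale <- 1
  for (iter in 1:4) {
    scaled <- rescale_cap(axes, scale)
    scale <- scale * spacing_deg / lattice_io_mean(scaled)
  }
  rescale_cap(axes, scale)
}

# Scale every axis's polar angle about the cap center (+x) by `c`.
rescale_cap <- function(axes, c) {
  t(apply(axes, 1, function(u) {
    theta <- acos(pmin(1, pmax(-1, u[1])))
    tang <- c(0, u[2], u[3])
    if (vnorm(tang) < 1e-12) return(c(1, 0, 0))
    tang <- unitize(tang)
    cos(c * theta) * c(1, 0, 0) + sin(c * theta) * tang
  }))
}

cap_lattice_raw <- function(n, spacing_deg, jitter_deg = 0) {
  a <- deg2rad(spacing_deg)
  row_step <- a * sqrt(3) / 2
  dirs <- list(c(1, 0, 0))
  k <- 1
  while (length(dirs) < n) {
    theta <- k * row_step
    if (theta >= pi) break
    m <- max(1L, round(2 * pi * sin(theta) / a))
    psi <- 2 * pi * (seq_len(m) - 1) / m + (k %% 2) * pi / m
    for (p in psi) {
      dirs[[length(dirs) + 1L]] <-
        c(cos(theta), sin(theta) * cos(p), sin(theta) * sin(p))
    }
    k <- k + 1
  }
  axes <- do.call(rbind, dirs[seq_len(n)])
  if (jitter_deg > 0) {
    # isotropic angular jitter: tilt each axis by N(0, jitter/sqrt(2)) in
    # two orthogonal tangent directions
    s <- deg2rad(jitter_deg) / sqrt(2)
    for (i in seq_len(n)) {
      u <- axes[i, ]
      e1 <- orthogonal_to(u)
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      axes[i, ] <- unitize(u + stats::rnorm(1, 0, s) * e1 +
                             stats::rnorm(1, 0, s) * e2)
    }
  }
  axes
}

#' Build synthetic lens markers from explicit axes
#'
#' Deterministic constructor used by [generate_synthetic_eye()] and
#' directly useful for fully controlled fixtures (e.g. two axes placed an
#' exact angle apart). Each lens is placed on a sphere of radius
#' `eye_radius` along its axis: six base markers on a circle of the given
#' diameter in the plane orthogonal to the axis, outer / inner tip markers
#' displaced along the axis by the half thicknesses, and a rhabdomere
#' marker at `rhabdomere_depth` along the inward axis.
#'
#' @param axes n x 3 matrix of unit visual-axis directions.
#' @param diameters Lens diameter(s), micrometres (recycled).
#' @param eye_radius Sphere radius for lens centers, micrometres.
#' @param outer_half_thickness,inner_half_thickness,rhabdomere_depth See
#'   [synthetic_eye_spec()].
#' @param marker_noise_sd Isotropic marker noise SD, micrometres.
#' @param ocelli Include the canonical ocelli triangle (default `TRUE`).
#' @return Long-format marker data.frame (see [marker_sets_from_table()]).
#' @export
synthetic_eye_from_axes <- function(axes, diameters, eye_radius = 28,
                                    outer_half_thickness = 1.61,
                                    inner_half_thickness = 1.28,
                                    rhabdomere_depth = 15,
                                    marker_noise_sd = 0,
                                    ocelli = TRUE) {
  axes <- as.matrix(axes)
  stop_field(ncol(axes) == 3, "axes", "must be an n x 3 matrix")
  n <- nrow(axes)
  diameters <- rep_len(diameters, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    u <- unitize(axes[i, ])
    ctr <- eye_radius * u
    e1 <- orthogonal_to(u)
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    phi <- deg2rad(seq(0, 300, by = 60))
    base <- t(vapply(phi, function(p) {
      ctr + (diameters[i] / 2) * (cos(p) * e1 + sin(p) * e2)
    }, numeric(3)))
    pts <- rbind(ctr + outer_half_thickness * u,
                 ctr - inner_half_thickness * u,
                 base,
                 ctr - rhabdomere_depth * u)
    rows[[i]] <- data.frame(
      ommatidium_id = i,
      marker_role = c("outer_tip", "inner_tip", paste0("base", 1:6),
                      "rhabdomere"),
      x = pts[, 1], y = pts[, 2], z = pts[, 3])
  }
  out <- do.call(rbind, rows)
  if (ocelli) {
    oc <- canonical_ocelli()
    out <- rbind(out, data.frame(ommatidium_id = NA_integer_,
                                 marker_role = paste0("ocellus", 1:3),
                                 x = oc[, 1], y = oc[, 2], z = oc[, 3]))
  }
  if (marker_noise_sd > 0) {
    m <- nrow(out)
    out$x <- out$x + stats::rnorm(m, 0, marker_noise_sd)
    out$y <- out$y + stats::rnorm(m, 0, marker_noise_sd)
    out$z <- out$z + stats::rnorm(m, 0, marker_noise_sd)
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic eye: landmark table plus ground truth
#'
#' Visual axes are placed on a jittered hexagonal lattice over a spherical
#' cap so that neighboring axes are spaced `target_io_angle` degrees apart
#' on average; lens diameters are drawn from the configured normal
#' distribution; the landmark set of every ommatidium is built with
#' [synthetic_eye_from_axes()]; independent isotropic Gaussian noise is
#' added to every marker. Ground truth (axes, lens centers, diameters, and
#' pairwise interommatidial angles over the Delaunay neighbor graph of the
#' true centers) is returned alongside for recovery testing.
#'
#' The sphere radius is set to `lens_diameter_mean / target_io_angle` (in
#' radians) so that adjacent lenses tile the eye surface without overlap.
#'
#' @param spec A [synthetic_eye_spec()].
#' @return list of class `synthetic_eye` with `markers` (long-format
#'   data.frame) and `truth` (list: `axes`, `centers`, `diameters`,
#'   `eye_radius`, `edges` data.frame with true per-edge `io_angle`,
#'   `io_mean`).
#' @export
generate_synthetic_eye <- function(spec) {
  stopifnot(inherits(spec, "synthetic_eye_spec"))
  with_seed(spec$seed, {
    axes <- cap_lattice_axes(spec$n_ommatidia, spec$target_io_angle,
                             spec$io_angle_sd)
    diameters <- stats::rnorm(spec$n_ommatidia, spec$lens_diameter_mean,
                              spec$lens_diameter_sd)
    diameters <- pmax(diameters, 0.2 * spec$lens_diameter_mean)
    eye_radius <- spec$lens_diameter_mean / deg2rad(spec$target_io_angle)
    markers <- synthetic_eye_from_axes(
      axes, diameters, eye_radius,
      spec$outer_half_thickness, spec$inner_half_thickness,
      spec$rhabdomere_depth, spec$marker_noise_sd)
    centers <- eye_radius * axes
    e <- build_neighbor_graph(centers, "delaunay")
    io <- vapply(seq_len(nrow(e)), function(r) {
      angle_between_deg(axes[e[r, 1], ], axes[e[r, 2], ])
    }, numeric(1))
    truth <- list(axes = axes, centers = centers, diameters = diameters,
                  eye_radius = eye_radius,
                  edges = data.frame(i = e[, 1], j = e[, 2], io_angle = io),
                  io_mean = mean(io))
    structure(list(markers = markers, truth = truth),
              class = "synthetic_eye")
  })
}
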