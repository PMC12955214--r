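#' Refractive indices used in the thin-lens focal-length calculation
#'
#' Defaults follow values adopted for hymenopteran compound eyes: corneal
#' lens 1.45, air 1.0, crystalline cone 1.35.
#'
#' @param n_lens Refractive index of the corneal lens.
#' @param n_air Refractive index of air.
#' @param n_cone Refractive index of the crystalline cone.
#' @return An object of class `optical_constants`.
#' @export
optical_constants <- function(n_lens = 1.45, n_air = 1.0, n_cone = 1.35) {
  stop_field(n_lens > n_cone && n_cone > n_air && n_air >= 1,
             "n_lens/n_cone/n_air", "require n_lens > n_cone > n_air >= 1")
  structure(list(n_lens = n_lens, n_air = n_air, n_cone = n_cone),
            class = "optical_constants")
}

#' Radius of curvature of a spherical lens dome
#'
#' A spherical cap of rim diameter `D` and apex height `h` above the rim
#' plane lies on a sphere of radius `r = (D^2/4 + h^2) / (2*h)`. Applied to
#' the outer and inner corneal surfaces with their respective half
#' thicknesses. `h = 0` denotes a flat surface and returns `Inf` (zero
#' curvature), not an error, so that downstream focal-length terms vanish.
#'
#' @param D Lens (rim) diameter, micrometres (> 0).
#' @param h Half thickness: distance of the lens tip from the lens principal
#'   plane, micrometres (>= 0).
#' @return Radius of curvature, micrometres. Vectorized.
#' @examples
#' radius_of_curvature(10, 5)   # hemisphere: r = D/2
#' radius_of_curvature(8, 1)    # 8.5
#' @export
radius_of_curvature <- function(D, h) {
  stop_field(all(D > 0), "D", "must be positive")
  stop_field(all(h >= 0), "h", "must be non-negative")
  ifelse(h == 0, Inf, (D^2 / 4 + h^2) / (2 * h))
}

#' Thin-lens focal length from the lens-maker formula
#'
#' `1/l = (n_lens - n_air)/r_air - (n_lens - n_cone)/r_cone`, where
#' `r_air` is the radius of curvature of the surface facing air and
#' `r_cone` the radius of the surface facing the crystalline cone.
#'
#' By default (`radius_assignment = "physical"`) the air term receives the
#' OUTER radius of curvature — air physically meets the outer corneal
#' surface — and the cone term the inner radius.
#' `radius_assignment = "literal"` feeds the air term the inner radius
#' instead, matching a labeling convention in which r1 denotes the inner
#' surface; this typically yields substantially longer focal lengths.
#' An infinite radius (flat surface) contributes zero curvature.
#'
#' @param r_outer Outer-surface radius of curvature, micrometres.
#' @param r_inner Inner-surface radius of curvature, micrometres.
#' @param constants An [optical_constants()] object.
#' @param radius_assignment `"physical"` (default) or `"literal"`.
#' @return Focal length, micrometres. Vectorized over the radii.
#' @examples
#' focal_length(7.10, 9.48)  # ~18.9 um
#' @export
focal_length <- function(r_outer, r_inner,
                         constants = optical_constants(),
                         radius_assignment = c("physical", "literal")) {
  radius_assignment <- match.arg(radius_assignment)
  stop_field(all(r_outer > 0) && all(r_inner > 0),
             "r_outer/r_inner", "must be positive")
  r_air <- if (radius_assignment == "physical") r_outer else r_inner
  r_cone <- if (radius_assignment == "physical") r_inner else r_outer
  air_term <- ifelse(is.finite(r_air),
                     (constants$n_lens - constants$n_air) / r_air, 0)
  cone_term <- ifelse(is.finite(r_cone),
                      (constants$n_lens - constants$n_cone) / r_cone, 0)
  inv_l <- air_term - cone_term
  if (any(inv_l <= 0)) {
    bad <- which(inv_l <= 0)[1]
    stop(sprintf(paste0("diverging lens: 1/l = %.4g <= 0 ",
                        "(r_air = %.4g, r_cone = %.4g)"),
                 inv_l[bad],
                 rep_len(r_air, length(inv_l))[bad],
                 rep_len(r_cone, length(inv_l))[bad]))
  }
  1 / inv_l
}

#' Geometric acceptance angle of an ommatidium
#'
#' Small-angle ratio of the rhabdomere spacing to the focal length:
#' `rho = d / l` radians, returned in degrees.
#'
#' @param d Distance between neighboring rhabdomeres, micrometres (> 0).
#' @param l Focal length, micrometres (> 0).
#' @return Acceptance angle, degrees. Vectorized.
#' @examples
#' acceptance_angle(5.79, 20.2)  # ~16.4 degrees
#' @export
acceptance_angle <- function(d, l) {
  stop_field(all(d > 0), "d", "must be positive")
  stop_field(all(l > 0), "l", "must be positive")
  rad2deg(d / l)
}

#' Per-ommatidium optics from reconstructed geometry
#'
#' Applies [radius_of_curvature()], [focal_length()] and
#' [acceptance_angle()] row-wise to a geometry table as produced by
#' [reconstruct_eye()].
#'
#' @param geometry data.frame with columns `ommatidium_id`, `lens_diameter`,
#'   `h_outer`, `h_inner` and (optionally) `rhabdomere_distance`
#'   (micrometres).
#' @param constants An [optical_constants()] object.
#' @param radius_assignment Passed to [focal_length()].
#' @return data.frame with columns `ommatidium_id`, `r_outer`, `r_inner`,
#'   `focal_length`, `acceptance_angle` (degrees; `NA` where the rhabdomere
#'   distance is unavailable).
#' @export
ommatidium_optics <- function(geometry, constants = optical_constants(),
                              radius_assignment = c("physical", "literal")) {
  radius_assignment <- match.arg(radius_assignment)
  need <- c("ommatidium_id", "lens_diameter", "h_outer", "h_inner")
  stop_field(all(need %in% names(geometry)), "geometry",
             paste("must contain columns", paste(need, collapse = ", ")))
  r_out <- radius_of_curvature(geometry$lens_diameter, geometry$h_outer)
  r_in <- radius_of_curvature(geometry$lens_diameter, geometry$h_inner)
  l <- focal_length(r_out, r_in, constants, radius_assignment)
  rho <- if ("rhabdomere_distance" %in% names(geometry)) {
    ifelse(is.na(geometry$rhabdomere_distance), NA_real_,
           acceptance_angle(pmax(geometry$rhabdomere_distance,
                                 .Machine$double.eps), l))
  } else {
    NA_real_
  }
  data.frame(ommatidium_id = geometry$ommatidium_id,
             r_outer = r_out, r_inner = r_in,
             focal_length = l, acceptance_angle = rho)
}

#' Eye-level summary of optical parameters
#'
#' Mean, SD, median and N per optical quantity, plus the two derived
#' ratios: focal length over lens diameter, and acceptance angle over
#' interommatidial angle. Ratios are reported both as ratios of the
#' per-quantity means (the convention used when quoting eye-level numbers)
#' and as means of per-ommatidium ratios.
#'
#' @param optics data.frame from [ommatidium_optics()].
#' @param geometry Geometry table with `lens_diameter` (same row order /
#'   ids as `optics`).
#' @param io_edges Optional per-edge interommatidial-angle table with a
#'   column `io_angle` (degrees), as from [interommatidial_angles()].
#' @return list with `table` (one row per quantity: mean, sd, median, n)
#'   and `ratios` (named numeric vector with `focal_over_diameter`,
#'   `acceptance_over_io` and their per-ommatidium counterparts where
#'   computable).
#' @export
summarize_optics <- function(optics, geometry, io_edges = NULL) {
  stop_field(nrow(optics) >= 1, "optics", "must contain at least one row")
  qty <- list(
    lens_diameter = geometry$lens_diameter,
    r_outer = optics$r_outer,
    r_inner = optics$r_inner,
    focal_length = optics$focal_length,
    acceptance_angle = optics$acceptance_angle
  )
  if (!is.null(io_edges)) qty$io_angle <- io_edges$io_angle
  tab <- do.call(rbind, lapply(names(qty), function(nm) {
    x <- qty[[nm]][is.finite(qty[[nm]])]
    data.frame(quantity = nm,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else 0,
               median = if (length(x)) stats::median(x) else NA_real_,
               n = length(x))
  }))
  means <- stats::setNames(tab$mean, tab$quantity)
  ratios <- c(focal_over_diameter =
                unname(means["focal_length"] / means["lens_diameter"]),
              focal_over_diameter_perlens =
                mean(optics$focal_length / geometry$lens_diameter,
                     na.rm = TRUE))
  if (!is.null(io_edges)) {
    ratios <- c(ratios, acceptance_over_io =
                  unname(means["acceptance_angle"] / means["io_angle"]))
  }
  list(table = tab, ratios = ratios)
}
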