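#' Split a long-format marker table into per-ommatidium marker sets
#'
#' The marker table has one row per digitized landmark with columns
#' `ommatidium_id`, `marker_role`, `x`, `y`, `z` (micrometres). Roles are
#' `outer_tip`, `inner_tip`, `base1`..`base6`, `rhabdomere` for lens
#' landmarks and `ocellus1`..`ocellus3` (with `ommatidium_id` `NA` or `0`)
#' for the head-frame ocelli.
#'
#' @param markers data.frame in the long marker schema.
#' @return list with `lenses` (named list of per-ommatidium marker sets:
#'   `outer_tip`, `inner_tip`, `base_points` (6 x 3), `rhabdomere_tip`) and
#'   `ocelli` (3 x 3 matrix or `NULL`).
#' @export
marker_sets_from_table <- function(markers) {
  need <- c("ommatidium_id", "marker_role", "x", "y", "z")
  stop_field(all(need %in% names(markers)), "markers",
             paste("must contain columns", paste(need, collapse = ", ")))
  stop_field(all(is.finite(c(markers$x, markers$y, markers$z))),
             "markers", "all coordinates must be finite")
  is_oc <- grepl("^ocellus", markers$marker_role)
  ocelli <- NULL
  if (any(is_oc)) {
    oc <- markers[is_oc, ]
    oc <- oc[order(oc$marker_role), ]
    stop_field(nrow(oc) == 3, "markers", "expected exactly three ocelli rows")
    ocelli <- as.matrix(oc[, c("x", "y", "z")])
  }
  lens_rows <- markers[!is_oc, ]
  lenses <- lapply(split(lens_rows, lens_rows$ommatidium_id), function(m) {
    pt <- function(role) {
      r <- m[m$marker_role == role, c("x", "y", "z")]
      if (nrow(r) != 1) {
        stop(sprintf("ommatidium %s: expected one `%s` marker, found %d",
                     m$ommatidium_id[1], role, nrow(r)))
      }
      as.numeric(r)
    }
    base <- m[grepl("^base[1-6]$", m$marker_role), ]
    stop_field(nrow(base) == 6, "markers",
               sprintf("ommatidium %s must have exactly six base points",
                       m$ommatidium_id[1]))
    base <- base[order(base$marker_role), ]
    list(ommatidium_id = m$ommatidium_id[1],
         outer_tip = pt("outer_tip"),
         inner_tip = pt("inner_tip"),
         base_points = as.matrix(base[, c("x", "y", "z")]),
         rhabdomere_tip = pt("rhabdomere"))
  })
  list(lenses = lenses, ocelli = ocelli)
}

#' Normalize head orientation from the three ocelli landmarks
#'
#' Builds the rigid transform that moves the ocelli centroid to the origin
#' and the ocelli-plane normal to +z, with the first ocellus defining the
#' +x direction within the plane, and applies it to every marker. No
#' scaling is performed.
#'
#' @param ocelli 3 x 3 matrix, one ocellus per row (micrometres).
#' @param markers Optional data.frame with columns `x`, `y`, `z` to
#'   transform alongside (e.g. a long marker table).
#' @return list with `frame` (list: `rotation` 3 x 3 with determinant +1,
#'   `origin` the ocelli centroid; points map as
#'   `rotation %*% (p - origin)`) and `markers` (the transformed table, or
#'   `NULL`).
#' @export
normalize_head <- function(ocelli, markers = NULL) {
  ocelli <- as.matrix(ocelli)
  stop_field(all(dim(ocelli) == c(3, 3)), "ocelli", "must be a 3 x 3 matrix")
  centroid <- colMeans(ocelli)
  e1 <- ocelli[2, ] - ocelli[1, ]
  e2 <- ocelli[3, ] - ocelli[1, ]
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  if (vnorm(nrm) < 1e-9 * max(vnorm(e1), vnorm(e2), 1)) {
    stop("degenerate head frame: ocelli are collinear")
  }
  zax <- unitize(nrm)
  x0 <- ocelli[1, ] - centroid
  x0 <- x0 - sum(x0 * zax) * zax
  if (vnorm(x0) < 1e-12) {
    stop("degenerate head frame: first ocellus lies on the plane normal axis")
  }
  xax <- unitize(x0)
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  rotation <- rbind(xax, yax, zax)
  dimnames(rotation) <- NULL
  out_markers <- NULL
  if (!is.null(markers)) {
    pts <- as.matrix(markers[, c("x", "y", "z")])
    tp <- t(rotation %*% (t(pts) - centroid))
    out_markers <- markers
    out_markers$x <- tp[, 1]
    out_markers$y <- tp[, 2]
    out_markers$z <- tp[, 3]
  }
  list(frame = list(rotation = rotation, origin = centroid),
       markers = out_markers)
}

#' Least-squares circle fit to the lens-base landmarks
#'
#' Fits the least-squares plane through the (six) base points, projects the
#' points into it — the orientation in which the projected base area is
#' maximal — and fits a circle in-plane by linear least squares. The circle
#' center is lifted back to 3-D and the plane normal is oriented outward
#' (toward `outer_tip` when supplied).
#'
#' @param base_points n x 3 matrix (n >= 3, typically 6), micrometres.
#' @param outer_tip Optional 3-vector used to orient the normal outward.
#' @param residual_tolerance In-plane radial RMSE (micrometres) above which
#'   the fit is flagged (not an error).
#' @return list: `center` (3-vector), `diameter`, `normal` (unit 3-vector),
#'   `rmse` (in-plane radial RMSE), `flagged` (logical).
#' @export
fit_lens_circle <- function(base_points, outer_tip = NULL,
                            residual_tolerance = Inf) {
  pts <- as.matrix(base_points)
  stop_field(ncol(pts) == 3 && nrow(pts) >= 3, "base_points",
             "must be an n x 3 matrix with n >= 3")
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate lens base: points are (near) collinear")
  }
  normal <- sv$v[, 3]
  uv <- centered %*% sv$v[, 1:2]
  # Kasa fit: x^2 + y^2 = 2 a x + 2 b y + c (linear least squares)
  rhs <- rowSums(uv^2)
  A <- cbind(2 * uv, 1)
  coef <- qr.solve(A, rhs)
  center2d <- coef[1:2]
  radius <- sqrt(coef[3] + sum(center2d^2))
  resid <- sqrt(rowSums(sweep(uv, 2, center2d)^2)) - radius
  rmse <- sqrt(mean(resid^2))
  center <- centroid + sv$v[, 1:2] %*% center2d
  if (!is.null(outer_tip) && sum(normal * (outer_tip - center)) < 0) {
    normal <- -normal
  }
  list(center = as.numeric(center), diameter = 2 * radius,
       normal = as.numeric(normal), rmse = rmse,
       flagged = rmse > residual_tolerance)
}

#' Visual axis of an ommatidium
#'
#' Default method `"top"`: the projection line from the fitted lens-base
#' circle center through the digitized outer lens tip. Method `"normal"`:
#' the lens-base plane normal, oriented outward (toward the outer tip).
#'
#' @param lens A per-ommatidium marker set (see [marker_sets_from_table()]).
#' @param circle A fit from [fit_lens_circle()].
#' @param method `"top"` (default) or `"normal"`.
#' @return Unit 3-vector.
#' @export
compute_visual_axis <- function(lens, circle, method = c("top", "normal")) {
  method <- match.arg(method)
  outward <- lens$outer_tip - circle$center
  if (vnorm(outward) < 1e-9) {
    stop("outer tip coincides with the lens-base circle center")
  }
  if (method == "top") {
    unitize(outward)
  } else {
    n <- unitize(circle$normal)
    if (sum(n * outward) < 0) n <- -n
    n
  }
}

#' Neighbor graph over lens centers
#'
#' Default `"delaunay"`: lens centers are referred to their best-fit sphere
#' center, projected into the tangent plane at their mean viewing direction
#' (azimuthal equidistant projection — faithful for the cap-like layout of
#' a compound eye), and triangulated in 2-D; edges are the triangulation
#' edges. `"knn"`: symmetric union of each center's `k` nearest neighbors
#' (Euclidean, 3-D), for partial or non-cap eyes.
#'
#' @param centers n x 3 matrix of lens centers (n >= 2).
#' @param method `"delaunay"` (default) or `"knn"`.
#' @param k Number of neighbors for `"knn"`.
#' @return Two-column integer matrix of edges (`i < j`), symmetric by
#'   construction, no self-edges.
#' @export
build_neighbor_graph <- function(centers, method = c("delaunay", "knn"),
                                 k = 6) {
  method <- match.arg(method)
  centers <- as.matrix(centers)
  n <- nrow(centers)
  stop_field(n >= 2, "centers", "need at least two ommatidia")
  if (n == 2) return(matrix(c(1L, 2L), 1, 2))
  if (n == 3) return(matrix(c(1L, 2L, 1L, 3L, 2L, 3L), 3, 2, byrow = TRUE))
  if (method == "knn") return(knn_edges(centers, k))
  sph <- tryCatch(fit_sphere(centers), error = function(e) NULL)
  proj <- if (is.null(sph)) {
    # coplanar layout: project onto the best-fit plane
    ctr <- colMeans(centers)
    sv <- svd(sweep(centers, 2, ctr))
    sweep(centers, 2, ctr) %*% sv$v[, 1:2]
  } else {
    dirs <- sweep(centers, 2, sph$center)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    u <- unitize(colMeans(dirs))
    rot <- rotation_between(u, c(0, 0, 1))
    d2 <- dirs %*% t(rot)
    theta <- acos(pmin(1, pmax(-1, d2[, 3])))
    rho <- sqrt(d2[, 1]^2 + d2[, 2]^2)
    scale <- ifelse(rho < 1e-12, 0, theta / pmax(rho, 1e-12))
    cbind(d2[, 1] * scale, d2[, 2] * scale)
  }
  edges <- tryCatch({
    dd <- deldir::deldir(proj[, 1], proj[, 2], suppressMsge = TRUE)
    cbind(dd$delsgs$ind1, dd$delsgs$ind2)
  }, error = function(e) knn_edges(centers, k))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  storage.mode(edges) <- "integer"
  edges
}

knn_edges <- function(centers, k) {
  n <- nrow(centers)
  k <- min(k, n - 1L)
  dmat <- as.matrix(stats::dist(centers))
  diag(dmat) <- Inf
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(dmat[i, ])[seq_len(k)]
    cbind(pmin(i, nb), pmax(i, nb))
  }))
  edges <- unique(pairs)
  storage.mode(edges) <- "integer"
  edges
}

# Linear least-squares sphere fit: |p|^2 = 2 p.c + k.
fit_sphere <- function(pts) {
  A <- cbind(2 * pts, 1)
  rhs <- rowSums(pts^2)
  coef <- qr.solve(A, rhs)
  center <- coef[1:3]
  r2 <- coef[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) stop("degenerate sphere fit")
  list(center = center, radius = sqrt(r2))
}

#' Reconstruct an eye model from a digitized marker table
#'
#' Runs the full landmark pipeline: (1) head orientation normalized from
#' the ocelli triangle (when present), (2) per-lens base plane / circle fit
#' in the maximal-area orientation, (3) lens diameter from the fitted
#' circle, (4) visual axis from the circle center and outer lens tip (or
#' the base normal). A neighbor graph over lens centers then yields
#' pairwise interommatidial angles and per-lens rhabdomere spacing (mean
#' 3-D distance to graph-neighbor rhabdomere tips).
#'
#' @param markers Long-format marker table (see [marker_sets_from_table()]).
#' @param axis_method `"top"` (default) or `"normal"`; see
#'   [compute_visual_axis()].
#' @param neighbor_method `"delaunay"` (default) or `"knn"`.
#' @param k Neighbor count for `"knn"`.
#' @param normalize_head_frame Apply ocelli-based normalization when ocelli
#'   markers are present (default `TRUE`).
#' @param residual_tolerance Passed to [fit_lens_circle()].
#' @return An object of class `eye_model`: list with `geometry` (per-lens
#'   data.frame: id, center, axis, `lens_diameter`, `h_outer`, `h_inner`,
#'   `rhabdomere_distance`, `circle_rmse`, `flagged`), `edges` (data.frame
#'   `i`, `j`, `io_angle` in degrees), `head_frame`, `axis_method`,
#'   `neighbor_method`.
#' @export
reconstruct_eye <- function(markers, axis_method = c("top", "normal"),
                            neighbor_method = c("delaunay", "knn"), k = 6,
                            normalize_head_frame = TRUE,
                            residual_tolerance = Inf) {
  axis_method <- match.arg(axis_method)
  neighbor_method <- match.arg(neighbor_method)
  sets <- marker_sets_from_table(markers)
  head_frame <- NULL
  if (normalize_head_frame && !is.null(sets$ocelli)) {
    nh <- normalize_head(sets$ocelli, markers)
    head_frame <- nh$frame
    sets <- marker_sets_from_table(nh$markers)
  }
  lenses <- sets$lenses
  stop_field(length(lenses) >= 1, "markers", "no ommatidium markers found")
  rows <- lapply(lenses, function(lens) {
    circ <- fit_lens_circle(lens$base_points, lens$outer_tip,
                            residual_tolerance)
    axis <- compute_visual_axis(lens, circ, axis_method)
    nrm <- unitize(circ$normal)
    data.frame(ommatidium_id = lens$ommatidium_id,
               cx = circ$center[1], cy = circ$center[2], cz = circ$center[3],
               ax = axis[1], ay = axis[2], az = axis[3],
               lens_diameter = circ$diameter,
               h_outer = abs(sum((lens$outer_tip - circ$center) * nrm)),
               h_inner = abs(sum((lens$inner_tip - circ$center) * nrm)),
               rx = lens$rhabdomere_tip[1], ry = lens$rhabdomere_tip[2],
               rz = lens$rhabdomere_tip[3],
               circle_rmse = circ$rmse, flagged = circ$flagged)
  })
  geometry <- do.call(rbind, rows)
  rownames(geometry) <- NULL
  edges <- NULL
  if (nrow(geometry) >= 2) {
    centers <- as.matrix(geometry[, c("cx", "cy", "cz")])
    e <- build_neighbor_graph(centers, neighbor_method, k)
    axes <- as.matrix(geometry[, c("ax", "ay", "az")])
    io <- vapply(seq_len(nrow(e)), function(r) {
      angle_between_deg(axes[e[r, 1], ], axes[e[r, 2], ])
    }, numeric(1))
    edges <- data.frame(i = e[, 1], j = e[, 2],
                        id_i = geometry$ommatidium_id[e[, 1]],
                        id_j = geometry$ommatidium_id[e[, 2]],
                        io_angle = io)
    rh <- as.matrix(geometry[, c("rx", "ry", "rz")])
    geometry$rhabdomere_distance <- vapply(seq_len(nrow(geometry)),
      function(i) {
        nb <- c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
        if (!length(nb)) return(NA_real_)
        mean(sqrt(rowSums((rh[nb, , drop = FALSE] -
                           matrix(rh[i, ], length(nb), 3, byrow = TRUE))^2)))
      }, numeric(1))
  } else {
    geometry$rhabdomere_distance <- NA_real_
  }
  structure(list(geometry = geometry, edges = edges,
                 head_frame = head_frame, axis_method = axis_method,
                 neighbor_method = neighbor_method),
            class = "eye_model")
}

#' Per-edge interommatidial angles and their summary
#'
#' @param model An `eye_model` from [reconstruct_eye()].
#' @return list with `edges` (data.frame `i`, `j`, `io_angle` degrees) and
#'   `summary` (`mean`, `sd`, `n` over edges). Angles are symmetric in edge
#'   orientation and lie in `[0, 180]` degrees.
#' @export
interommatidial_angles <- function(model) {
  stopifnot(inherits(model, "eye_model"))
  stop_field(!is.null(model$edges), "model", "neighbor graph not built")
  io <- model$edges$io_angle
  list(edges = model$edges,
       summary = list(mean = mean(io),
                      sd = if (length(io) > 1) stats::sd(io) else 0,
                      n = length(io)))
}

#' Spherical eye-map projection
#'
#' Visual-axis directions in the normalized head frame expressed as
#' azimuth (`atan2(ay, ax)`) and elevation (`asin(az)`), both in degrees,
#' joined with lens diameter (and focal length when an optics table is
#' supplied) for plotting against the eye map.
#'
#' @param model An `eye_model`.
#' @param optics Optional [ommatidium_optics()] table to join on
#'   `ommatidium_id`.
#' @return data.frame with `ommatidium_id`, `azimuth`, `elevation`,
#'   `lens_diameter` (and `focal_length` when available).
#' @export
eye_map_projection <- function(model, optics = NULL) {
  stopifnot(inherits(model, "eye_model"))
  g <- model$geometry
  out <- data.frame(ommatidium_id = g$ommatidium_id,
                    azimuth = rad2deg(atan2(g$ay, g$ax)),
                    elevation = rad2deg(asin(pmin(1, pmax(-1, g$az)))),
                    lens_diameter = g$lens_diameter)
  if (!is.null(optics)) {
    out <- merge(out, optics[, c("ommatidium_id", "focal_length")],
                 by = "ommatidium_id", sort = FALSE)
  }
  out
}

#' Unit axis from azimuth / elevation
#'
#' Inverse of the [eye_map_projection()] convention: azimuth 0, elevation 0
#' maps to +x; elevation 90 maps to +z.
#'
#' @param azimuth,elevation Angles in degrees.
#' @return n x 3 matrix of unit vectors.
#' @export
axis_from_azel <- function(azimuth, elevation) {
  az <- deg2rad(azimuth)
  el <- deg2rad(elevation)
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}
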