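# The two axial-slice comparison methods (Jakob; Goutallier), computed on
# cross-sections of the aligned meshes.  All 2D work happens in the plane
# basis of plane_coords(), where in-plane angles equal the package's
# transverse azimuth convention (external rotation positive).

line2d <- function(point, direction, plane) {
  d <- direction / sqrt(sum(direction^2))
  structure(list(point = as.numeric(point), direction = as.numeric(d),
                 azimuth = deg(atan2(d[2], d[1])), plane = plane),
            class = "line2d")
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d through (%.2f, %.2f), azimuth %.2f deg>\n",
              x$point[1], x$point[2], x$azimuth))
  invisible(x)
}

line2d_to_axis3 <- function(l) {
  b <- plane_basis(l$plane$normal)
  p3 <- l$plane$point + l$point[1] * b$e1 + l$point[2] * b$e2
  d3 <- l$direction[1] * b$e1 + l$direction[2] * b$e2
  axis3(p3, d3)
}

axial_plane <- function(y) plane3(c(0, y, 0), c(0, 1, 0))

largest_contour <- function(contours) {
  areas <- vapply(contours, contour_area, numeric(1))
  contours[[which.max(areas)]]
}

#' Proximal 2D axis: posterior tangent of the tibial head
#'
#' The slice level is 1 mm proximal to the fibular head apex (the most
#' proximal fibular vertex).  The tangent is the trimmed total-least-
#' squares line through the posterior-facing part of the tibial contour's
#' convex hull (outward normals within 45 degrees of posterior) -- a
#' reproducible stand-in for the manually placed tangent along the
#' posterior cortex.
#'
#' @param tibia,fibula aligned [surface_mesh()] objects.
#' @param config a [run_config()] (`slice_offset_mm`).
#' @return A `line2d` (point, direction and azimuth in the axial plane).
#' @export
proximal_axis_2d <- function(tibia, fibula, config = run_config()) {
  stopifnot(inherits(tibia, "surface_mesh"))
  if (is.null(fibula)) {
    stop("proximal 2D axis: the fibula mesh defines the slice level and is required",
         call. = FALSE)
  }
  y_star <- max(fibula$vertices[, 2]) + config$slice_offset_mm
  pl <- axial_plane(y_star)
  cts <- slice_mesh(tibia, pl)
  if (length(cts) == 0) {
    stop(sprintf("proximal slice error: no tibial contour at y = %.1f mm (fibular head apex + %g mm)",
                 y_star, config$slice_offset_mm), call. = FALSE)
  }
  poly <- largest_contour(cts)$polygon
  hull <- rev(grDevices::chull(poly))  # counter-clockwise order
  hp <- poly[hull, , drop = FALSE]
  nh <- nrow(hp)
  nxt <- c(2:nh, 1)
  ed <- hp[nxt, , drop = FALSE] - hp
  len <- sqrt(rowSums(ed^2))
  # outward normal of a CCW polygon edge is the edge direction rotated -90;
  # posterior is +e2 in the axial plane basis (e2 = normal x e1 = -z)
  outward <- cbind(ed[, 2], -ed[, 1]) / len
  keep <- outward[, 2] > 0.707  # posterior-facing within 45 degrees
  if (!any(keep)) keep <- outward[, 2] >= max(outward[, 2]) - 1e-12
  fit <- arc_tangent_center(edge_point_set(hp[keep, , drop = FALSE],
                                           hp[nxt[keep], , drop = FALSE], len[keep]))
  line2d(point = fit$center, direction = fit$direction, plane = pl)
}

fit_contour_circle <- function(contour) {
  fit_circle_2d(contour$polygon)
}

#' Distal 2D axis, Jakob technique
#'
#' Circles are fitted to the tibial and fibular contours in the slice
#' 1 mm proximal to the distal articular surface (the distal tibia joint
#' plane level); the axis is the line connecting the two circle centres
#' (tibia to fibula).
#'
#' @param tibia,fibula aligned [surface_mesh()] objects.
#' @param dtjp the distal tibia joint plane ([fit_dtjp()]).
#' @param config a [run_config()].
#' @return A `line2d`.
#' @export
jakob_distal_axis <- function(tibia, fibula, dtjp, config = run_config()) {
  stopifnot(inherits(tibia, "surface_mesh"), inherits(dtjp, "plane3"))
  if (is.null(fibula)) {
    stop("Jakob distal axis: fibula mesh required", call. = FALSE)
  }
  y_star <- dtjp$point[2] + config$slice_offset_mm
  pl <- axial_plane(y_star)
  ct_t <- slice_mesh(tibia, pl)
  if (length(ct_t) == 0) {
    stop(sprintf("Jakob slice error: no tibial contour at y = %.1f mm", y_star), call. = FALSE)
  }
  ct_f <- slice_mesh(fibula, pl)
  if (length(ct_f) == 0) {
    stop(sprintf("Jakob slice error: no fibular contour at y = %.1f mm", y_star), call. = FALSE)
  }
  c_t <- fit_contour_circle(largest_contour(ct_t))$center
  c_f <- fit_contour_circle(largest_contour(ct_f))$center
  d <- c_f - c_t
  if (sqrt(sum(d^2)) < 1e-9) stop("Jakob distal axis: coincident circle centres", call. = FALSE)
  line2d(point = (c_t + c_f) / 2, direction = d, plane = pl)
}

# articular aspect of a closed contour: all edges whose outward normals
# point within 45 degrees of the direction toward the target (the
# inter-malleolar midpoint); returned as edge midpoints with length
# weights.  Contiguity is not required -- vertex noise can split the
# facet into runs -- and stray curved edges are removed by the trimmed
# refit downstream.
articular_arc <- function(poly, target) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  mid <- (poly + poly[nxt, , drop = FALSE]) / 2
  ed <- poly[nxt, , drop = FALSE] - poly
  len <- sqrt(rowSums(ed^2))
  ccw <- polygon_area(poly) > 0
  outward <- if (ccw) cbind(ed[, 2], -ed[, 1]) else cbind(-ed[, 2], ed[, 1])
  outward <- outward / len
  to_mid <- sweep(-mid, 2, target, `+`)
  to_mid <- to_mid / sqrt(rowSums(to_mid^2))
  keep <- rowSums(outward * to_mid) > 0.707  # within 45 degrees
  if (!any(keep)) return(NULL)
  edge_point_set(poly[keep, , drop = FALSE], poly[nxt[keep], , drop = FALSE], len[keep])
}

# represent kept edges by their endpoints with half-length weights, so a
# single edge still defines a line
edge_point_set <- function(p0, p1, len) {
  list(pts = rbind(p0, p1), w = rep(len / 2, 2))
}

weighted_tls_line <- function(pts, w) {
  ctr <- colSums(pts * w) / sum(w)
  xc <- sweep(pts, 2, ctr)
  C <- crossprod(xc * w, xc)
  e <- eigen(C, symmetric = TRUE)
  list(center = ctr, direction = e$vectors[, 1])
}

# robust tangent: iteratively reweighted total-least-squares line with a
# Tukey biweight on the orthogonal residual.  The smooth weights make the
# tangent a continuous function of the contour (no hard inclusion
# threshold), so jittered corner or curved-rim edges fade out instead of
# flipping in and out.  The tangent centre is the robust weighted centroid
# (which lies on the fitted line).
arc_tangent_center <- function(arc) {
  pts <- arc$pts
  w0 <- arc$w
  fit <- weighted_tls_line(pts, w0)
  for (it in 1:5) {
    xc <- sweep(pts, 2, fit$center)
    resid <- abs(xc[, 1] * -fit$direction[2] + xc[, 2] * fit$direction[1])
    scale <- max(1.0, 3 * sqrt(sum(w0 * resid^2) / sum(w0)))
    wb <- w0 * pmax(1 - (resid / scale)^2, 0)^2
    if (sum(wb > 0) < 2) break
    fit <- weighted_tls_line(pts, wb)
  }
  list(center = fit$center, direction = fit$direction)
}

#' Distal 2D axis, Goutallier technique
#'
#' In the slice 1 mm distal of the distal articular surface, tangents are
#' placed on the articular aspects of the medial malleolus (tibial
#' contour) and the lateral malleolus (fibular contour); the axis is the
#' line connecting the centres of the two tangents.  The articular aspect
#' of each contour is the arc whose outward normals point toward the
#' inter-malleolar midpoint; the tangent is a robust (Tukey-biweight)
#' total-least-squares line on that arc and its centre is the robust
#' centroid of the arc on the tangent.
#'
#' @param tibia,fibula aligned [surface_mesh()] objects.
#' @param dtjp the distal tibia joint plane ([fit_dtjp()]).
#' @param config a [run_config()].
#' @return A `line2d`.
#' @export
goutallier_distal_axis <- function(tibia, fibula, dtjp, config = run_config()) {
  stopifnot(inherits(tibia, "surface_mesh"), inherits(dtjp, "plane3"))
  if (is.null(fibula)) {
    stop("Goutallier distal axis: fibula mesh required", call. = FALSE)
  }
  y_star <- dtjp$point[2] - config$slice_offset_mm
  pl <- axial_plane(y_star)
  ct_t <- slice_mesh(tibia, pl)
  if (length(ct_t) == 0) {
    stop(sprintf("Goutallier slice error: no medial malleolus contour at y = %.1f mm", y_star),
         call. = FALSE)
  }
  ct_f <- slice_mesh(fibula, pl)
  if (length(ct_f) == 0) {
    stop(sprintf("Goutallier slice error: no lateral malleolus contour at y = %.1f mm", y_star),
         call. = FALSE)
  }
  poly_m <- largest_contour(ct_t)$polygon
  poly_l <- largest_contour(ct_f)$polygon
  # inter-malleolar midpoint approximated from the contour centroids
  mid <- (colMeans(poly_m) + colMeans(poly_l)) / 2
  arc_m <- articular_arc(poly_m, mid)
  arc_l <- articular_arc(poly_l, mid)
  if (is.null(arc_m)) stop("Goutallier: no articular aspect found on the medial malleolus", call. = FALSE)
  if (is.null(arc_l)) stop("Goutallier: no articular aspect found on the lateral malleolus", call. = FALSE)
  tm <- arc_tangent_center(arc_m)
  tl <- arc_tangent_center(arc_l)
  d <- tl$center - tm$center
  if (sqrt(sum(d^2)) < 1e-9) stop("Goutallier distal axis: coincident tangent centres", call. = FALSE)
  line2d(point = (tm$center + tl$center) / 2, direction = d, plane = pl)
}

measure_torsion_2d_aligned <- function(b, frame, dtjp, method, config = run_config()) {
  if (is.null(b$fibula)) {
    stop(sprintf("[input] the %s method requires a fibula mesh", method), call. = FALSE)
  }
  prox <- run_stage("proximal tangent", proximal_axis_2d(b$tibia, b$fibula, config = config))
  dist <- run_stage(
    sprintf("%s distal axis", method),
    if (method == "jakob") jakob_distal_axis(b$tibia, b$fibula, dtjp, config = config)
    else goutallier_distal_axis(b$tibia, b$fibula, dtjp, config = config))
  # line directions carry a 180-degree ambiguity: report in (-90, 90]
  angle <- wrap90(dist$azimuth - prox$azimuth)
  torsion_result(angle, method, pta = line2d_to_axis3(prox), dta = line2d_to_axis3(dist),
                 anatomical_axis = NULL, frame = frame,
                 diagnostics = list(proximal_slice_y_mm = prox$plane$point[2],
                                    distal_slice_y_mm = dist$plane$point[2],
                                    proximal_azimuth_deg = prox$azimuth,
                                    distal_azimuth_deg = dist$azimuth))
}

#' Measure tibial torsion with a 2D reference technique
#'
#' Aligns the bones, computes the shared proximal posterior tangent and
#' the method's distal axis (Jakob: line through the tibial and fibular
#' circle centres 1 mm proximal to the ankle joint surface; Goutallier:
#' line through the malleolar tangent centres 1 mm distal of it), and
#' reports the signed angle from the proximal to the distal axis in the
#' axial plane, external positive, in (-90, 90].
#'
#' @param bones a [bone_set()] with tibia, fibula and landmarks.
#' @param method `"jakob"` or `"goutallier"`.
#' @param seed integer seed (the 2D chain is deterministic).
#' @param config a [run_config()].
#' @return A `torsion_result`.
#' @export
measure_torsion_2d <- function(bones, method = c("jakob", "goutallier"), seed = 1,
                               config = run_config()) {
  method <- match.arg(method)
  al <- run_stage("alignment", align_to_reference(bones))
  dtjp <- run_stage("distal joint plane", fit_dtjp(al$bones$landmarks))
  measure_torsion_2d_aligned(al$bones, al$frame, dtjp, method, config = config)
}
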