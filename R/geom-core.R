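#' Weighted point set
#'
#' A set of 3D points in millimetres with optional positive per-point
#' weights.  Weights let surface integrals (area-weighted moments) flow
#' through the same PCA code path as plain point clouds.
#'
#' @param points n x 3 numeric matrix (mm).
#' @param weights optional positive weights, one per point.
#' @return An object of class `point_set`.
#' @export
point_set <- function(points, weights = NULL) {
  points <- as_point_matrix(points)
  if (nrow(points) == 0) stop("point set must be nonempty", call. = FALSE)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(points)) stop("weights must match point count", call. = FALSE)
    if (!all(is.finite(weights)) || any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  }
  structure(list(points = points, weights = weights), class = "point_set")
}

as_point_set <- function(x) {
  if (inherits(x, "point_set")) x else point_set(x)
}

#' Oriented axis (line) in 3D
#' @param point a point on the axis (mm).
#' @param direction direction vector; normalised on construction.
#' @return An object of class `axis3`.
#' @export
axis3 <- function(point, direction) {
  structure(list(point = as.numeric(point), direction = unit3(as.numeric(direction))),
            class = "axis3")
}

#' @export
print.axis3 <- function(x, ...) {
  cat(sprintf("<axis3 through (%.2f, %.2f, %.2f) along (%.4f, %.4f, %.4f)>\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Oriented plane in 3D
#' @param point a point on the plane (mm).
#' @param normal normal vector; normalised on construction.
#' @return An object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unit3(as.numeric(normal))),
            class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3 through (%.2f, %.2f, %.2f) normal (%.4f, %.4f, %.4f)>\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

planar_contour <- function(plane, polygon, closed = TRUE) {
  polygon <- as.matrix(polygon)
  if (closed && nrow(polygon) < 3) stop("closed contour needs at least 3 points", call. = FALSE)
  structure(list(plane = plane, polygon = polygon, closed = closed),
            class = "planar_contour")
}

weighted_moments <- function(points, weights = NULL) {
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  center <- colSums(points * w)
  xc <- sweep(points, 2, center)
  cov <- crossprod(xc * w, xc)  # population (weight-normalised) covariance
  list(center = center, cov = cov)
}

#' Principal component axes of a point set
#'
#' Weighted (population) PCA.  Components are orthonormal, ordered by
#' descending variance, and each component's sign is fixed by a
#' deterministic convention: positive dot product with +x, then +y, then
#' +z, whichever is first nonzero.  Eigenvectors are sign-ambiguous and
#' axis orientations must not flip run to run, hence the convention.
#'
#' @param points a [point_set()] or n x 3 matrix (n >= 3).
#' @return List with `center` (3-vector), `components` (3 x 3 matrix,
#'   columns are the components) and `variances` (length 3, descending).
#' @export
pca_axes <- function(points) {
  ps <- as_point_set(points)
  if (nrow(ps$points) < 3) stop("pca_axes needs at least 3 points", call. = FALSE)
  m <- weighted_moments(ps$points, ps$weights)
  e <- eigen(m$cov, symmetric = TRUE)
  comps <- e$vectors
  vars <- pmax(e$values, 0)
  for (j in 1:3) comps[, j] <- fix_sign(comps[, j])
  list(center = m$center, components = comps, variances = vars)
}

fix_sign <- function(v, tol = 1e-9) {
  for (k in 1:3) {
    if (abs(v[k]) > tol) {
      if (v[k] < 0) v <- -v
      return(v)
    }
  }
  v
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal distances
#' (centroid plus smallest-variance principal component as normal).  The
#' normal sign is fixed to point into the half-space of `ref_direction`.
#'
#' @param points a [point_set()] or matrix of at least 3 non-collinear points.
#' @param ref_direction direction the returned normal should have a
#'   non-negative dot product with (default +y).
#' @return A [plane3()] with attribute `"rms_residual"` (mm).
#' @export
fit_plane <- function(points, ref_direction = c(0, 1, 0)) {
  ps <- as_point_set(points)
  if (nrow(ps$points) < 3) stop("fit_plane needs at least 3 points", call. = FALSE)
  p <- pca_axes(ps)
  scale2 <- max(p$variances[1], .Machine$double.eps)
  if (p$variances[2] / scale2 < 1e-12) {
    stop("fit_plane: points are collinear, plane fit is degenerate", call. = FALSE)
  }
  normal <- p$components[, 3]
  if (sum(normal * ref_direction) < 0) normal <- -normal
  pl <- plane3(p$center, normal)
  attr(pl, "rms_residual") <- sqrt(p$variances[3])
  pl
}

kmeanspp_init <- function(x) {
  n <- nrow(x)
  i1 <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[i1, ])^2)
  if (all(d2 == 0)) stop("kmeans2: all points are identical", call. = FALSE)
  i2 <- sample.int(n, 1, prob = d2)
  rbind(x[i1, ], x[i2, ])
}

#' Two-cluster k-means with k-means++ initialisation
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ starting
#' centres, squared Euclidean distance, at most `iter_max` iterations,
#' best of `nstart` seeded restarts by within-cluster sum of squares.
#' Deterministic given `seed`.  Cluster 1 is the cluster whose centre has
#' the larger x (ties broken by y then z), so labels are reproducible.
#'
#' @param points a [point_set()] or n x 3 matrix of at least 2 distinct points.
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @return List with `labels` (1/2 per point), `centers` (2 x 3) and
#'   `wcss` (total within-cluster sum of squares).
#' @export
kmeans2 <- function(points, seed = 1, nstart = 10, iter_max = 300) {
  x <- as_point_set(points)$points
  if (nrow(x) < 2) stop("kmeans2 needs at least 2 points", call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(nstart)) {
      centers0 <- kmeanspp_init(x)
      if (sum((centers0[1, ] - centers0[2, ])^2) == 0) next
      km <- suppressWarnings(
        stats::kmeans(x, centers = centers0, iter.max = iter_max, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("kmeans2: could not find two distinct clusters", call. = FALSE)
  # canonical cluster order: larger x first, then y, then z
  o <- order(-best$centers[, 1], -best$centers[, 2], -best$centers[, 3])
  labels <- match(best$cluster, o)
  list(labels = labels, centers = unname(best$centers[o, , drop = FALSE]),
       wcss = best$tot.withinss)
}

#' Least-squares circle fit in 2D
#'
#' Algebraic (Pratt-style) circle fit followed by one Gauss-Newton
#' refinement pass on geometric distance.  Works on partial arcs; full
#' circle coverage is not required.
#'
#' @param points n x 2 matrix of at least 3 non-collinear points.
#' @return List with `center` (length 2) and `radius` (mm).
#' @export
fit_circle_2d <- function(points) {
  x <- as.matrix(points)
  if (ncol(x) != 2) stop("fit_circle_2d expects 2D points", call. = FALSE)
  if (nrow(x) < 3) stop("fit_circle_2d needs at least 3 points", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)$d
  if (sv[2] / max(sv[1], .Machine$double.eps) < 1e-9) {
    stop("fit_circle_2d: points are collinear, circle fit is degenerate", call. = FALSE)
  }
  s <- max(sv[1] / sqrt(nrow(x)), 1e-12)
  u <- xc / s
  z <- rowSums(u^2)
  A <- cbind(z, u[, 1], u[, 2], 1)
  S <- crossprod(A) / nrow(A)
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4)
  p <- tryCatch({
    ev <- eigen(solve(B, S))
    vals <- ev$values; vecs <- ev$vectors
    ok <- abs(Im(vals)) < 1e-8
    vals <- Re(vals[ok]); vecs <- Re(vecs[, ok, drop = FALSE])
    pos <- which(vals > -1e-12)
    if (!length(pos)) stop("no admissible eigenvalue")
    vecs[, pos[which.min(vals[pos])]]
  }, error = function(e) {
    # Kasa fallback: linear least squares on x^2+y^2 = 2ax + 2by + c
    co <- stats::lsfit(cbind(2 * u[, 1], 2 * u[, 2]), z)$coefficients
    c(-1, 2 * co[2], 2 * co[3], 2 * co[1]) * -0.5  # to (a,b,c,d) form
  })
  a <- p[1]; b <- p[2]; c_ <- p[3]; d <- p[4]
  if (abs(a) < 1e-14) stop("fit_circle_2d: degenerate (line-like) algebraic fit", call. = FALSE)
  cen_u <- c(-b, -c_) / (2 * a)
  r_u <- sqrt(max(b^2 + c_^2 - 4 * a * d, 0)) / (2 * abs(a))
  cen <- cen_u * s + ctr
  r <- r_u * s
  # one Gauss-Newton pass on geometric distances
  dx <- x[, 1] - cen[1]; dy <- x[, 2] - cen[2]
  ri <- sqrt(dx^2 + dy^2)
  ok <- ri > 1e-12
  J <- cbind(-dx[ok] / ri[ok], -dy[ok] / ri[ok], -1)
  res <- ri[ok] - r
  step <- tryCatch(solve(crossprod(J), crossprod(J, res)), error = function(e) rep(0, 3))
  cen <- cen - step[1:2]
  r <- r - step[3]
  list(center = as.numeric(cen), radius = as.numeric(r))
}

#' Intersect a mesh with a plane
#'
#' Computes all closed intersection polygons of the triangulated surface
#' with the plane.  Intersections are computed once per crossing edge, so
#' contours chain exactly; vertices lying numerically on the plane are
#' nudged to one side (1e-9 mm) for robustness.  Each returned contour is
#' oriented counter-clockwise about the plane normal (signed area >= 0).
#'
#' @param mesh a [surface_mesh()].
#' @param plane a [plane3()].
#' @return List of `planar_contour` objects (possibly empty).  Each
#'   contour stores the plane, its 2D polygon in the plane basis of
#'   [plane_coords()], and 3D points as attribute `"points3d"`.
#' @export
slice_mesh <- function(mesh, plane) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(plane, "plane3"))
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.vector(sweep(v, 2, plane$point) %*% plane$normal)
  d[abs(d) < 1e-9] <- 1e-9
  s <- d > 0
  cross_face <- (s[f[, 1]] + s[f[, 2]] + s[f[, 3]]) %in% c(1L, 2L)
  if (!any(cross_face)) return(list())
  f <- f[cross_face, , drop = FALSE]
  # crossing edges, keyed canonically
  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  crossing <- s[ea[, 1]] != s[ea[, 2]]
  ekey <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  nf <- nrow(f)
  seg_by_face <- split(ekey[crossing], rep(seq_len(nf), 3)[crossing])
  segs <- do.call(rbind, seg_by_face[lengths(seg_by_face) == 2])
  if (is.null(segs) || nrow(segs) == 0) return(list())
  # unique crossing edges -> intersection points
  ue <- unique(ekey[crossing])
  ue_idx <- match(ue, ekey)
  i1 <- ea[ue_idx, 1]; i2 <- ea[ue_idx, 2]
  t <- d[i1] / (d[i1] - d[i2])
  pts <- v[i1, , drop = FALSE] + (v[i2, , drop = FALSE] - v[i1, , drop = FALSE]) * t
  # adjacency between edge keys through faces
  a <- match(segs[, 1], ue)
  b <- match(segs[, 2], ue)
  nbr <- vector("list", length(ue))
  for (i in seq_along(a)) {
    nbr[[a[i]]] <- c(nbr[[a[i]]], b[i])
    nbr[[b[i]]] <- c(nbr[[b[i]]], a[i])
  }
  visited <- logical(length(ue))
  basis <- plane_basis(plane$normal)
  contours <- list()
  for (start in seq_along(ue)) {
    if (visited[start] || length(nbr[[start]]) < 2) next
    loop <- integer(0)
    cur <- start
    prev <- 0L
    closed <- FALSE
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nx <- setdiff(nbr[[cur]], prev)
      nx <- nx[!visited[nx]]
      if (!length(nx)) {
        closed <- start %in% nbr[[cur]] && length(loop) >= 3
        break
      }
      prev <- cur
      cur <- nx[1]
    }
    if (!closed) next
    p3 <- pts[loop, , drop = FALSE]
    rel <- sweep(p3, 2, plane$point)
    p2 <- cbind(rel %*% basis$e1, rel %*% basis$e2)
    if (polygon_area(p2) < 0) {
      p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
      p3 <- p3[rev(seq_len(nrow(p3))), , drop = FALSE]
    }
    ct <- planar_contour(plane, p2, closed = TRUE)
    attr(ct, "points3d") <- p3
    contours[[length(contours) + 1]] <- ct
  }
  contours
}

#' In-plane coordinate basis of a plane
#'
#' Deterministic right-handed basis `(e1, e2, normal)` used for all 2D
#' computations on a plane; `e1` tracks global +x where possible.  For an
#' axial plane (normal +y) the plane coordinates are `(x, -z)`, so
#' in-plane angles equal the package's transverse azimuth convention.
#'
#' @param plane a [plane3()].
#' @return List with unit vectors `e1` and `e2`.
#' @export
plane_coords <- function(plane) plane_basis(plane$normal)

polygon_area <- function(p2) {
  x <- p2[, 1]; y <- p2[, 2]
  i2 <- c(seq_len(nrow(p2))[-1], 1)
  0.5 * sum(x * y[i2] - x[i2] * y)
}

#' Area centroid of a closed planar contour
#'
#' Shoelace-formula area centroid of the polygon, mapped back to 3D world
#' coordinates.
#'
#' @param contour a `planar_contour` from [slice_mesh()].
#' @return Length-3 point (mm).
#' @export
contour_centroid <- function(contour) {
  stopifnot(inherits(contour, "planar_contour"))
  if (!contour$closed) stop("contour_centroid requires a closed contour", call. = FALSE)
  p2 <- contour$polygon
  x <- p2[, 1]; y <- p2[, 2]
  i2 <- c(seq_len(nrow(p2))[-1], 1)
  cr <- x * y[i2] - x[i2] * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) stop("contour_centroid: zero-area contour", call. = FALSE)
  cx <- sum((x + x[i2]) * cr) / (6 * a)
  cy <- sum((y + y[i2]) * cr) / (6 * a)
  basis <- plane_basis(contour$plane$normal)
  contour$plane$point + cx * basis$e1 + cy * basis$e2
}

contour_area <- function(contour) abs(polygon_area(contour$polygon))

# squared distances and closest points from one query point to many triangles
point_triangles_closest <- function(p, A, B, C) {
  e1 <- B - A
  e2 <- C - A
  ap <- sweep(-A, 2, p, `+`)  # p - A
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  b1 <- rowSums(e1 * ap); b2 <- rowSums(e2 * ap)
  det <- pmax(a11 * a22 - a12^2, 1e-300)
  s <- (a22 * b1 - a12 * b2) / det
  t <- (a11 * b2 - a12 * b1) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  cand <- A + e1 * s + e2 * t
  # closest point on each edge segment
  seg_closest <- function(P0, P1) {
    d <- P1 - P0
    w <- sweep(-P0, 2, p, `+`)
    tt <- rowSums(w * d) / pmax(rowSums(d * d), 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    P0 + d * tt
  }
  c1 <- seg_closest(A, B); c2 <- seg_closest(B, C); c3 <- seg_closest(C, A)
  d2 <- function(X) rowSums(sweep(X, 2, p)^2)
  dmat <- cbind(ifelse(inside, d2(cand), Inf), d2(c1), d2(c2), d2(c3))
  pick <- max.col(-dmat, ties.method = "first")
  n <- nrow(A)
  out <- matrix(0, n, 3)
  for (k in 1:4) {
    sel <- pick == k
    if (!any(sel)) next
    src <- switch(k, cand, c1, c2, c3)
    out[sel, ] <- src[sel, , drop = FALSE]
  }
  list(points = out, dist2 = dmat[cbind(seq_len(n), pick)])
}

#' Closest points on a triangulated surface
#'
#' For each query point, the nearest point on the surface (interiors,
#' edges and vertices of the triangles, not vertices only).  Candidate
#' faces are pre-filtered with a centroid-radius bound; the returned
#' points are exact minimisers over all faces.
#'
#' @param query a [point_set()] or matrix of query points.
#' @param mesh a [surface_mesh()].
#' @return A [point_set()] of the same length and order as the query.
#' @export
closest_surface_points <- function(query, mesh) {
  q <- as_point_set(query)
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  cent <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - cent)^2), rowSums((B - cent)^2), rowSums((C - cent)^2)))
  out <- matrix(0, nrow(q$points), 3)
  for (i in seq_len(nrow(q$points))) {
    p <- q$points[i, ]
    dc <- sqrt(rowSums(sweep(cent, 2, p)^2))
    ub <- min(dc + rad)
    sel <- dc - rad <= ub
    res <- point_triangles_closest(p, A[sel, , drop = FALSE], B[sel, , drop = FALSE],
                                   C[sel, , drop = FALSE])
    out[i, ] <- res$points[which.min(res$dist2), ]
  }
  point_set(out, weights = q$weights)
}

#' Area-uniform random samples on a surface
#'
#' Draws `n` points uniformly by area: faces are chosen with probability
#' proportional to area, positions within a face by the square-root
#' barycentric trick.  Deterministic given `seed`, and invariant under
#' rigid transforms of the mesh (the same faces and barycentric
#' coordinates are drawn).
#'
#' @param mesh a [surface_mesh()].
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return A [point_set()] of `n` points.
#' @export
sample_surface <- function(mesh, n, seed = 1) {
  stopifnot(inherits(mesh, "surface_mesh"), n >= 1)
  areas <- face_areas(mesh$vertices, mesh$faces)
  with_seed(seed, {
    fi <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
  })
  A <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
  pts <- A * (1 - r1) + B * (r1 * (1 - r2)) + C * (r1 * r2)
  point_set(pts)
}

#' Project a direction onto the plane perpendicular to a normal
#'
#' Removes the component of `v` along `normal` and renormalises.  Errors
#' if `v` is (numerically) parallel to `normal`.
#'
#' @param v 3D vector.
#' @param normal unit normal of the projection plane.
#' @return Unit 3-vector lying in the plane.
#' @export
project_direction <- function(v, normal) {
  n <- unit3(normal)
  w <- v - sum(v * n) * n
  if (vnorm(w) < 1e-9 * max(vnorm(v), 1e-300)) {
    stop("project_direction: vector is parallel to the plane normal", call. = FALSE)
  }
  unit3(w)
}

#' Signed angle between two directions about an axis
#'
#' Angle (degrees, in (-180, 180]) rotating `a` onto `b`, positive
#' counter-clockwise about `axis` (right-hand rule).  Both vectors are
#' expected to be perpendicular to the axis (use [project_direction()]
#' upstream).
#'
#' @param a,b unit vectors.
#' @param axis unit rotation axis.
#' @return Angle in degrees.
#' @export
signed_angle_about <- function(a, b, axis) {
  if (vnorm(a) < 1e-12 || vnorm(b) < 1e-12) {
    stop("signed_angle_about: zero-length input", call. = FALSE)
  }
  a <- unit3(a); b <- unit3(b); ax <- unit3(axis)
  deg(atan2(sum(cross3(a, b) * ax), sum(a * b)))
}
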