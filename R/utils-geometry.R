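# Internal geometry and numeric helpers shared across the package.
# All coordinates are millimetres; all angles at the API surface are degrees.

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# wrap to (-180, 180]
wrap180 <- function(a) {
  r <- a %% 360
  ifelse(r > 180, r - 360, r)
}

# wrap to (-90, 90] (line/axis angles, 180-degree ambiguity resolved)
wrap90 <- function(a) {
  r <- wrap180(a)
  r[r > 90] <- r[r > 90] - 180
  r[r <= -90] <- r[r <= -90] + 180
  r
}

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n < tol) {
    stop("cannot normalise a zero-length vector", call. = FALSE)
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Azimuth convention used throughout: an azimuth a (degrees) denotes the
# transverse direction (cos a, 0, -sin a) in the reference frame (+x lateral,
# +y proximal, +z anterior).  Increasing azimuth rotates the lateral end of
# an axis posteriorly, i.e. corresponds to external rotation of the segment
# that owns the axis.
azimuth_dir <- function(az) c(cos(rad(az)), 0, -sin(rad(az)))

# inverse: azimuth (degrees) of a transverse 3D direction, ignoring y
azimuth_of <- function(v) deg(atan2(-v[3], v[1]))

# same convention in 2D axial-plane coordinates (x, z)
azimuth_dir2 <- function(az) c(cos(rad(az)), -sin(rad(az)))
azimuth_of2 <- function(v) deg(atan2(-v[2], v[1]))

# Rodrigues rotation matrix about unit axis by angle (radians)
rotation_about <- function(axis, angle) {
  u <- unit3(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# minimal rotation mapping unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    axis <- unit3(cross3(a, p))
    return(rotation_about(axis, pi))
  }
  rotation_about(v / s, atan2(s, c_))
}

# Evaluate code with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

as_point_matrix <- function(x, arg = "points") {
  if (is.null(dim(x))) {
    if (length(x) %% 3 != 0) {
      stop(sprintf("'%s' must be an n x 3 matrix of coordinates", arg), call. = FALSE)
    }
    x <- matrix(x, ncol = 3, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(sprintf("'%s' must have 3 columns", arg), call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (!all(is.finite(x))) stop(sprintf("'%s' contains non-finite coordinates", arg), call. = FALSE)
  x
}

# right-handed in-plane basis (e1, e2) with e1 x e2 = normal.
# e1 tracks the global +x direction where possible (so that for an axial
# plane with normal +y, plane coordinates are (x, -z) and in-plane azimuths
# equal the package azimuth convention).
plane_basis <- function(normal) {
  n <- unit3(normal)
  seed_dir <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- unit3(seed_dir - sum(seed_dir * n) * n)
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

# areas of triangles given vertex matrix and 1-based face index matrix
face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Degree-2 exact surface quadrature: the three edge midpoints of each
# triangle with weight area/3 integrate any quadratic exactly, so weighted
# first and second moments (hence PCA) over the triangulated surface are
# exact, not sampled.
triangle_quadrature <- function(vertices, faces) {
  if (nrow(faces) == 0) {
    return(list(points = matrix(numeric(0), 0, 3), weights = numeric(0)))
  }
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  w <- face_areas(vertices, faces) / 3
  pts <- rbind((a + b) / 2, (b + c_) / 2, (c_ + a) / 2)
  w <- rep(w, 3)
  keep <- w > 1e-12  # clipped slivers contribute nothing
  list(points = pts[keep, , drop = FALSE], weights = w[keep])
}

# Clip triangles to the half-space dot(x, n) <= h (Sutherland-Hodgman per
# triangle, re-fanned).  Returns a triangle soup (vertices, faces).
# Vertices within 1e-6 mm of the clip plane count as inside, so geometry
# lying exactly on a boundary (e.g. a flat cap on the slab plane) is kept
# stably under rounding.
clip_triangles_halfspace <- function(vertices, faces, n, h) {
  if (nrow(faces) == 0) return(list(vertices = vertices, faces = faces[0, , drop = FALSE]))
  out_v <- vector("list", nrow(faces))
  out_f <- vector("list", nrow(faces))
  base <- 0L
  d_all <- as.vector(vertices %*% n) - h
  d_all[abs(d_all) <= 1e-6] <- 0
  for (i in seq_len(nrow(faces))) {
    idx <- faces[i, ]
    d <- d_all[idx]
    if (all(d <= 0)) {
      poly <- vertices[idx, , drop = FALSE]
    } else if (all(d > 0)) {
      next
    } else {
      poly_in <- vertices[idx, , drop = FALSE]
      keep <- list()
      for (j in 1:3) {
        k <- if (j == 3) 1 else j + 1
        dj <- d[j]; dk <- d[k]
        if (dj <= 0) keep[[length(keep) + 1]] <- poly_in[j, ]
        if ((dj <= 0) != (dk <= 0)) {
          t <- dj / (dj - dk)
          keep[[length(keep) + 1]] <- poly_in[j, ] + t * (poly_in[k, ] - poly_in[j, ])
        }
      }
      poly <- do.call(rbind, keep)
    }
    np <- nrow(poly)
    if (np < 3) next
    tri <- cbind(rep(base + 1L, np - 2L), base + seq_len(np - 2L) + 1L, base + seq_len(np - 2L) + 2L)
    out_v[[i]] <- poly
    out_f[[i]] <- tri
    base <- base + np
  }
  out_v <- out_v[!vapply(out_v, is.null, logical(1))]
  out_f <- out_f[!vapply(out_f, is.null, logical(1))]
  if (length(out_v) == 0) {
    return(list(vertices = matrix(numeric(0), 0, 3), faces = matrix(integer(0), 0, 3)))
  }
  list(vertices = do.call(rbind, out_v), faces = do.call(rbind, out_f))
}

# Clip triangles to a slab h_lo <= dot(x, n) <= h_hi
clip_triangles_slab <- function(vertices, faces, n, h_lo, h_hi) {
  s <- clip_triangles_halfspace(vertices, faces, n, h_hi)
  clip_triangles_halfspace(s$vertices, s$faces, -n, -h_lo)
}
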