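# Shared fixtures, built in code.  Phantoms are cached per test run (they
# are deterministic given the spec).

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]])) .phantom_cache[[key]] <- generate_phantom(spec)
  .phantom_cache[[key]]
}

# independent angle wrap used by tests (axis angles compare modulo 180)
wrap_axis_deg <- function(a) {
  r <- a %% 180
  ifelse(r > 90, r - 180, r)
}

angle_err <- function(measured, truth) abs(wrap_axis_deg(measured - truth))

# apply a rigid transform (and optional translation) to a whole bone set,
# using only the public API
transform_bone_set <- function(bones, R, tr) {
  tf_mesh <- function(m) {
    if (is.null(m)) return(NULL)
    surface_mesh(sweep(m$vertices %*% t(R), 2, tr, `+`), m$faces, m$name, clean = FALSE)
  }
  tf_pts <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, 1, 3)
    sweep(p %*% t(R), 2, tr, `+`)
  }
  lm <- bones$landmarks
  bone_set(tf_mesh(bones$tibia), tf_mesh(bones$femur), tf_mesh(bones$fibula),
           landmark_set(tf_pts(lm$distal_articular), tf_pts(lm$plateau),
                        as.vector(tf_pts(lm$knee_center)), as.vector(tf_pts(lm$anterior_ref)),
                        as.vector(tf_pts(lm$ankle_center)), side = lm$side),
           check_proximity = FALSE)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# closed regular tetrahedron as the smallest valid mesh
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  list(vertices = v, faces = f)
}

# open cylinder tube of radius r about the y axis, analytic fixture for
# slicing and sampling tests
cylinder_mesh <- function(r = 10, y0 = -50, y1 = 50, n_theta = 96, n_y = 11, closed = TRUE) {
  t <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ys <- seq(y1, y0, length.out = n_y)
  v <- do.call(rbind, lapply(ys, function(y) cbind(r * cos(t), y, r * sin(t))))
  f <- NULL
  jj <- seq_len(n_theta); j2 <- c(jj[-1], 1L)
  for (i in seq_len(n_y - 1)) {
    o1 <- (i - 1) * n_theta; o2 <- i * n_theta
    f <- rbind(f, cbind(o1 + jj, o2 + jj, o2 + j2), cbind(o1 + jj, o2 + j2, o1 + j2))
  }
  if (closed) {
    tc <- nrow(v) + 1L; bc <- nrow(v) + 2L
    v <- rbind(v, c(0, y1, 0), c(0, y0, 0))
    ob <- (n_y - 1) * n_theta
    f <- rbind(f, cbind(tc, j2, jj), cbind(bc, ob + jj, ob + j2))
  }
  surface_mesh(v, f, "cylinder")
}

# every undirected edge shared by exactly two faces with opposite direction
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ukey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  dkey <- paste(e[, 1], e[, 2])
  all(table(ukey) == 2) && !anyDuplicated(dkey)
}
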