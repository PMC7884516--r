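# Parametric synthetic bone phantom: tibia (lofted elliptical sections with
# a posterior head facet, a rotated distal metaphyseal band, a flat plafond
# and a separate medial malleolar block), distal femur (two condylar
# spheroids) and fibula (cylinder with head apex and a flat lateral
# malleolar facet).  Every axis the pipeline estimates has an analytic
# counterpart computed from the construction parameters.

#' Specification of a synthetic bone phantom
#'
#' All azimuths are in degrees under the package convention: azimuth `a`
#' is the transverse direction `(cos a, 0, -sin a)` with +x lateral, +y
#' proximal, +z anterior, so increasing azimuth is external rotation.
#'
#' @param torsion convenience parameter: if given, sets
#'   `condyle_azimuth = 0`, `posterior_facet_azimuth = 0`,
#'   `distal_major_azimuth = torsion - 90` (so the distal ellipse minor
#'   axis, which defines the default 3D distal axis, sits at `torsion`)
#'   and `fibula_azimuth = torsion`, making the construction truth of the
#'   tibia-only 3D method and of both 2D methods equal to `torsion`.
#' @param side `"right"` or `"left"` (left phantoms are mirrored in x).
#' @param shaft_length tibia length plateau-to-plafond, mm (>= 160).
#' @param plateau_halfwidth plateau ellipse semi-major axis, mm.
#' @param condyle_azimuth azimuth of the femoral condyle centre line
#'   (ground truth of the proximal tibia axis).
#' @param condyle_spacing distance between condyle centres, mm.
#' @param posterior_facet_azimuth azimuth of the flat posterior cortex
#'   facet of the tibial head (2D proximal tangent truth).
#' @param distal_major_azimuth azimuth of the distal ellipse major axis.
#' @param distal_semi_axes semi-axes (major, minor) of the distal band
#'   ellipse, mm; major must exceed minor.
#' @param fibula_azimuth azimuth of the fibula centre relative to the
#'   tibia centre (Jakob circle-centre line truth, and the malleolar
#'   facet line truth).
#' @param fibula_offset tibia-centre-to-fibula-centre distance, mm.
#' @param fibula_radius fibula cylinder radius, mm.
#' @param shaft_tilt whole-phantom tilt about +x, degrees.
#' @param noise_sd Gaussian vertex noise, mm (0 = noise-free).
#' @param mesh_density target boundary edge length, mm (smaller = finer).
#' @param seed integer seed for the vertex noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(torsion = NULL,
                         side = c("right", "left"),
                         shaft_length = 360,
                         plateau_halfwidth = 38,
                         condyle_azimuth = 0,
                         condyle_spacing = 44,
                         posterior_facet_azimuth = 0,
                         distal_major_azimuth = -90,
                         distal_semi_axes = c(25, 18),
                         fibula_azimuth = 0,
                         fibula_offset = 40,
                         fibula_radius = 8,
                         shaft_tilt = 0,
                         noise_sd = 0,
                         mesh_density = 2.5,
                         seed = 1) {
  side <- match.arg(side)
  if (!is.null(torsion)) {
    condyle_azimuth <- 0
    posterior_facet_azimuth <- 0
    distal_major_azimuth <- torsion - 90
    fibula_azimuth <- torsion
  }
  if (shaft_length < 160) {
    stop("phantom spec: shaft_length must be at least 160 mm", call. = FALSE)
  }
  if (length(distal_semi_axes) != 2 || any(distal_semi_axes <= 0) ||
      distal_semi_axes[1] <= distal_semi_axes[2]) {
    stop("phantom spec: distal_semi_axes must be positive with major > minor", call. = FALSE)
  }
  if (noise_sd < 0) stop("phantom spec: noise_sd must be >= 0", call. = FALSE)
  if (mesh_density <= 0) stop("phantom spec: mesh_density must be positive", call. = FALSE)
  structure(list(side = side, shaft_length = shaft_length,
                 plateau_halfwidth = plateau_halfwidth,
                 condyle_azimuth = condyle_azimuth,
                 condyle_spacing = condyle_spacing,
                 posterior_facet_azimuth = posterior_facet_azimuth,
                 distal_major_azimuth = distal_major_azimuth,
                 distal_semi_axes = distal_semi_axes,
                 fibula_azimuth = fibula_azimuth,
                 fibula_offset = fibula_offset,
                 fibula_radius = fibula_radius,
                 shaft_tilt = shaft_tilt,
                 noise_sd = noise_sd,
                 mesh_density = mesh_density,
                 seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec: %s, L=%g mm, condyle az %g, distal minor az %g, fibula az %g, noise %g mm>\n",
              x$side, x$shaft_length, x$condyle_azimuth,
              wrap180(x$distal_major_azimuth + 90), x$fibula_azimuth, x$noise_sd))
  invisible(x)
}

az2 <- function(az) c(cos(rad(az)), -sin(rad(az)))  # raw (x, z) direction

ellipse_ring <- function(n, a, b, az, center = c(0, 0), facet = NULL) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- az2(az); w <- az2(az + 90)
  p <- cbind(center[1] + a * cos(t) * u[1] + b * sin(t) * w[1],
             center[2] + a * cos(t) * u[2] + b * sin(t) * w[2])
  if (!is.null(facet)) p <- clamp_ring(p, facet$normal, facet$offset)
  p
}

clamp_ring <- function(p, n2, h) {
  s <- p %*% n2
  over <- as.vector(s) > h
  if (any(over)) {
    p[over, ] <- p[over, , drop = FALSE] -
      outer(as.vector(s)[over] - h, n2)
  }
  p
}

box_ring <- function(center, u, hu, hv, nseg = 8) {
  v <- c(-u[2], u[1])
  corners <- rbind(center + hu * u + hv * v,
                   center - hu * u + hv * v,
                   center - hu * u - hv * v,
                   center + hu * u - hv * v)
  pts <- NULL
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    tt <- seq(0, 1, length.out = nseg + 1)[-(nseg + 1)]
    pts <- rbind(pts, sweep(outer(tt, corners[j, ] - corners[i, ]), 2, corners[i, ], `+`))
  }
  pts
}

mesh_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

orient_outward <- function(v, f) {
  if (mesh_volume(v, f) < 0) f <- f[, c(1, 3, 2)]
  list(vertices = v, faces = f)
}

# loft rings (list of n x 2 (x,z) polygons) at descending y levels into a
# closed triangulated tube with fan caps
build_loft <- function(levels, rings, top_center = NULL, bottom_center = NULL) {
  n <- nrow(rings[[1]])
  L <- length(levels)
  verts <- do.call(rbind, lapply(seq_len(L), function(i) {
    cbind(rings[[i]][, 1], levels[i], rings[[i]][, 2])
  }))
  faces <- NULL
  jj <- seq_len(n)
  j2 <- c(jj[-1], 1L)
  for (i in seq_len(L - 1)) {
    o1 <- (i - 1L) * n
    o2 <- i * n
    faces <- rbind(faces,
                   cbind(o1 + jj, o2 + jj, o2 + j2),
                   cbind(o1 + jj, o2 + j2, o1 + j2))
  }
  if (is.null(top_center)) top_center <- c(colMeans(rings[[1]]))
  if (is.null(bottom_center)) bottom_center <- c(colMeans(rings[[L]]))
  tc <- nrow(verts) + 1L
  bc <- nrow(verts) + 2L
  verts <- rbind(verts,
                 c(top_center[1], levels[1], top_center[2]),
                 c(bottom_center[1], levels[L], bottom_center[2]))
  ob <- (L - 1L) * n
  faces <- rbind(faces,
                 cbind(tc, jj, j2),
                 cbind(bc, ob + j2, ob + jj))
  orient_outward(verts, faces)
}

build_uv_sphere <- function(center, r, n_lon = 28, n_lat = 14) {
  lat <- seq(0, pi, length.out = n_lat + 1)
  ring_lat <- lat[2:n_lat]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  verts <- c(center + c(0, r, 0))
  verts <- matrix(verts, 1, 3)
  for (ph in ring_lat) {
    ring <- cbind(center[1] + r * sin(ph) * cos(lon),
                  center[2] + r * cos(ph),
                  center[3] + r * sin(ph) * sin(lon))
    verts <- rbind(verts, ring)
  }
  verts <- rbind(verts, center + c(0, -r, 0))
  south <- nrow(verts)
  faces <- NULL
  jj <- seq_len(n_lon); j2 <- c(jj[-1], 1L)
  # top cap
  faces <- rbind(faces, cbind(1L, 1L + jj, 1L + j2))
  nr <- length(ring_lat)
  for (i in seq_len(nr - 1)) {
    o1 <- 1L + (i - 1L) * n_lon
    o2 <- 1L + i * n_lon
    faces <- rbind(faces,
                   cbind(o1 + jj, o2 + jj, o2 + j2),
                   cbind(o1 + jj, o2 + j2, o1 + j2))
  }
  ob <- 1L + (nr - 1L) * n_lon
  faces <- rbind(faces, cbind(south, ob + j2, ob + jj))
  orient_outward(verts, faces)
}

merge_components <- function(...) {
  parts <- list(...)
  v <- NULL; f <- NULL
  for (p in parts) {
    f <- rbind(f, p$faces + if (is.null(v)) 0L else nrow(v))
    v <- rbind(v, p$vertices)
  }
  list(vertices = v, faces = f)
}

# interpolate section parameters along the tibia
tibia_sections <- function(spec) {
  a_p <- spec$plateau_halfwidth
  b_p <- a_p * 30 / 38
  a_h <- a_p * 24 / 38
  b_h <- a_p * 20 / 38
  list(a_p = a_p, b_p = b_p, a_h = a_h, b_h = b_h,
       a_s = 14, b_s = 12,
       facet_offset = 0.8 * b_h,
       y_plateau_lo = -6, y_head_hi = -15, y_head_lo = -35,
       y_shaft_hi = -60)
}

tibia_ring_at <- function(y, spec, sec, n) {
  L <- spec$shaft_length
  dma <- spec$distal_major_azimuth
  lerp <- function(t, u, v) u + t * (v - u)
  if (y >= sec$y_plateau_lo) {
    par <- c(sec$a_p, sec$b_p, 0)
  } else if (y >= sec$y_head_hi) {
    t <- (sec$y_plateau_lo - y) / (sec$y_plateau_lo - sec$y_head_hi)
    par <- c(lerp(t, sec$a_p, sec$a_h), lerp(t, sec$b_p, sec$b_h), 0)
  } else if (y >= sec$y_head_lo) {
    par <- c(sec$a_h, sec$b_h, 0)
  } else if (y >= sec$y_shaft_hi) {
    t <- (sec$y_head_lo - y) / (sec$y_head_lo - sec$y_shaft_hi)
    par <- c(lerp(t, sec$a_h, sec$a_s), lerp(t, sec$b_h, sec$b_s), 0)
  } else if (y >= -(L - 20)) {
    par <- c(sec$a_s, sec$b_s, 0)
  } else if (y >= -(L - 10)) {
    t <- (-(L - 20) - y) / 10
    par <- c(lerp(t, sec$a_s, spec$distal_semi_axes[1]),
             lerp(t, sec$b_s, spec$distal_semi_axes[2]),
             lerp(t, 0, wrap180(dma)))
  } else {
    par <- c(spec$distal_semi_axes[1], spec$distal_semi_axes[2], wrap180(dma))
  }
  facet <- NULL
  if (y <= sec$y_head_hi && y >= sec$y_head_lo) {
    facet <- list(normal = az2(spec$posterior_facet_azimuth + 90),
                  offset = sec$facet_offset)
  }
  ellipse_ring(n, par[1], par[2], par[3], facet = facet)
}

build_tibia <- function(spec, n_theta) {
  sec <- tibia_sections(spec)
  L <- spec$shaft_length
  sp <- spec$mesh_density
  levels <- unique(sort(c(
    seq(0, sec$y_plateau_lo, by = -min(sp, 2)),
    seq(sec$y_plateau_lo, sec$y_head_hi, by = -min(sp, 3)),
    seq(sec$y_head_hi, sec$y_head_lo, by = -min(sp, 2.5)),
    seq(sec$y_head_lo, sec$y_shaft_hi, by = -min(sp, 3)),
    seq(sec$y_shaft_hi, -(L - 20), by = -min(4 * sp, 12)),
    -(L - 20),
    seq(-(L - 20), -(L - 10), by = -min(sp, 2.5)),
    seq(-(L - 10), -L, by = -min(sp, 2)),
    -L), decreasing = TRUE))
  rings <- lapply(levels, tibia_ring_at, spec = spec, sec = sec, n = n_theta)
  main <- build_loft(levels, rings,
                     top_center = c(0, 0), bottom_center = c(0, 0))
  # medial malleolar block: a separate component below the plafond
  u <- az2(spec$fibula_azimuth)
  mal_levels <- c(-L - 0.5, -L - 4, -L - 8, -L - 12)
  mal_ring <- box_ring(center = -14 * u, u = u, hu = 6, hv = 6, nseg = 8)
  mal <- build_loft(mal_levels, rep(list(mal_ring), length(mal_levels)))
  merge_components(main, mal)
}

build_fibula <- function(spec, n_theta) {
  L <- spec$shaft_length
  u <- az2(spec$fibula_azimuth)
  center <- spec$fibula_offset * u
  r <- spec$fibula_radius
  sp <- spec$mesh_density
  cut_h <- -(spec$fibula_offset - r / 2)  # clamp dot(p, -u) <= cut_h
  levels <- unique(sort(c(
    seq(-20, -32, by = -min(sp, 3)),
    seq(-32, -(L - 16), by = -min(4 * sp, 12)),
    -(L - 16),
    seq(-(L - 16), -(L - 2), by = -min(sp, 2)),
    -L + 0.8, -L - 0.5,
    seq(-L - 2.5, -L - 12, by = -min(sp, 2.5)),
    -L - 12), decreasing = TRUE))
  rings <- lapply(levels, function(y) {
    facet <- if (y <= -L - 0.5) list(normal = -u, offset = cut_h) else NULL
    ellipse_ring(n_theta, r, r, 0, center = center, facet = facet)
  })
  build_loft(levels, rings)
}

build_femur <- function(spec) {
  u <- az2(spec$condyle_azimuth)
  r <- 16
  half <- spec$condyle_spacing / 2
  c1 <- c(half * u[1], r + 2, half * u[2])
  c2 <- c(-half * u[1], r + 2, -half * u[2])
  merge_components(build_uv_sphere(c1, r), build_uv_sphere(c2, r))
}

phantom_landmarks <- function(spec) {
  L <- spec$shaft_length
  sec <- tibia_sections(spec)
  ell_pts <- function(m, a, b, az, y) {
    t <- 2 * pi * (seq_len(m) - 1) / m
    u <- az2(az); w <- az2(az + 90)
    cbind(0.8 * (a * cos(t) * u[1] + b * sin(t) * w[1]),
          y,
          0.8 * (a * cos(t) * u[2] + b * sin(t) * w[2]))
  }
  list(distal_articular = ell_pts(9, spec$distal_semi_axes[1], spec$distal_semi_axes[2],
                                  spec$distal_major_azimuth, -L),
       plateau = ell_pts(8, sec$a_p, sec$b_p, 0, 0),
       knee_center = c(0, 0, 0),
       ankle_center = c(0, -L, 0),
       anterior_ref = c(0, -10, 40))
}

#' Generate a synthetic bone phantom
#'
#' Builds watertight tibia (with a separate medial malleolar block), distal
#' femur (two condylar spheroids) and fibula meshes plus auto-placed
#' landmarks from a [phantom_spec()], together with the analytic ground
#' truth for every axis and torsion angle the pipeline estimates.  Ground
#' truth is defined relative to the pipeline's axis definitions
#' (construction-internal consistency), not to any anatomical truth, and
#' is computed from the construction parameters: closed forms for the 2D
#' methods and exact part-wise surface moments for the 3D distal axis.
#' Vertex noise (`noise_sd`) is Gaussian and seeded; the generator is
#' deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return List with `bones` (a [bone_set()]), `ground_truth` (named list
#'   of azimuths and torsion angles in degrees) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_theta <- max(48L, 4L * round(24 * 2.5 / spec$mesh_density))
  n_fib <- max(36L, 4L * round(12 * 2.5 / spec$mesh_density))
  tib <- build_tibia(spec, n_theta)
  fib <- build_fibula(spec, n_fib)
  fem <- build_femur(spec)
  lm <- phantom_landmarks(spec)
  # whole-phantom tilt about +x
  if (spec$shaft_tilt != 0) {
    R <- rotation_about(c(1, 0, 0), rad(spec$shaft_tilt))
    rot <- function(m) m %*% t(R)
    tib$vertices <- rot(tib$vertices); fib$vertices <- rot(fib$vertices)
    fem$vertices <- rot(fem$vertices)
    lm$distal_articular <- rot(lm$distal_articular)
    lm$plateau <- rot(lm$plateau)
    lm$knee_center <- as.vector(R %*% lm$knee_center)
    lm$ankle_center <- as.vector(R %*% lm$ankle_center)
    lm$anterior_ref <- as.vector(R %*% lm$anterior_ref)
  }
  # mirror for left side (faces re-oriented by the winding flip)
  if (spec$side == "left") {
    mir <- function(m) { m[, 1] <- -m[, 1]; m }
    tib$vertices <- mir(tib$vertices); fib$vertices <- mir(fib$vertices)
    fem$vertices <- mir(fem$vertices)
    tib$faces <- tib$faces[, c(1, 3, 2)]
    fib$faces <- fib$faces[, c(1, 3, 2)]
    fem$faces <- fem$faces[, c(1, 3, 2)]
    lm$distal_articular <- mir(lm$distal_articular)
    lm$plateau <- mir(lm$plateau)
    lm$knee_center[1] <- -lm$knee_center[1]
    lm$ankle_center[1] <- -lm$ankle_center[1]
    lm$anterior_ref[1] <- -lm$anterior_ref[1]
  }
  if (spec$noise_sd > 0) {
    noisy <- function(m, k) {
      with_seed(spec$seed * 7 + k,
                m + matrix(stats::rnorm(length(m), sd = spec$noise_sd), nrow(m)))
    }
    tib$vertices <- noisy(tib$vertices, 1)
    fib$vertices <- noisy(fib$vertices, 2)
    fem$vertices <- noisy(fem$vertices, 3)
  }
  bones <- bone_set(
    tibia = surface_mesh(tib$vertices, tib$faces, "tibia"),
    femur = surface_mesh(fem$vertices, fem$faces, "femur"),
    fibula = surface_mesh(fib$vertices, fib$faces, "fibula"),
    landmarks = landmark_set(lm$distal_articular, lm$plateau, lm$knee_center,
                             lm$anterior_ref, lm$ankle_center, side = spec$side),
    check_proximity = FALSE)
  list(bones = bones, ground_truth = phantom_ground_truth(spec), spec = spec)
}

# exact part-wise surface moments of the distal slab (band wall + plafond
# disc, optionally the fibula band wall), in the canonical right-side frame
slab_parts <- function(spec, include_fibula) {
  a <- spec$distal_semi_axes[1]; b <- spec$distal_semi_axes[2]
  dma <- spec$distal_major_azimuth
  L <- spec$shaft_length
  h <- 10
  u3 <- azimuth_dir(dma); w3 <- azimuth_dir(dma + 90)
  R <- cbind(u3, w3, c(0, 1, 0))  # ellipse frame -> world
  m <- 4096
  t <- 2 * pi * (seq_len(m) - 0.5) / m
  wt <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  vxi <- sum(wt * (a * cos(t))^2) / sum(wt)
  veta <- sum(wt * (b * sin(t))^2) / sum(wt)
  perim <- sum(wt) * (2 * pi / m)
  rot_cov <- function(vx, ve, vy) R %*% diag(c(vx, ve, vy)) %*% t(R)
  parts <- list(
    list(w = perim * h, c = c(0, -L + h / 2, 0), C = rot_cov(vxi, veta, h^2 / 12)),
    list(w = pi * a * b, c = c(0, -L, 0), C = rot_cov(a^2 / 4, b^2 / 4, 0)))
  if (include_fibula) {
    r <- spec$fibula_radius
    fc <- spec$fibula_offset * azimuth_dir(spec$fibula_azimuth)
    parts <- c(parts, list(
      list(w = 2 * pi * r * h, c = c(fc[1], -L + h / 2, fc[3]),
           C = diag(c(r^2 / 2, h^2 / 12, r^2 / 2)))))
  }
  parts
}

combine_parts_cov <- function(parts) {
  wsum <- sum(vapply(parts, `[[`, numeric(1), "w"))
  cbar <- Reduce(`+`, lapply(parts, function(p) p$w * p$c)) / wsum
  C <- Reduce(`+`, lapply(parts, function(p) {
    d <- p$c - cbar
    p$w * (p$C + outer(d, d))
  })) / wsum
  list(center = cbar, cov = C)
}

truth_dta_azimuth <- function(spec, include_fibula, component_index = 2) {
  m <- combine_parts_cov(slab_parts(spec, include_fibula))
  e <- eigen(m$cov, symmetric = TRUE)
  comp <- fix_sign(e$vectors[, component_index])
  azimuth_of(comp)
}

phantom_ground_truth <- function(spec) {
  az_pta <- wrap90(spec$condyle_azimuth)
  az_t <- truth_dta_azimuth(spec, include_fibula = FALSE)
  az_tf <- truth_dta_azimuth(spec, include_fibula = TRUE)
  list(
    pta_azimuth = az_pta,
    posterior_tangent_azimuth = wrap90(spec$posterior_facet_azimuth),
    dta_azimuth_3d_t = az_t,
    dta_azimuth_3d_tf = az_tf,
    distal_axis_azimuth_jakob = wrap90(spec$fibula_azimuth),
    distal_axis_azimuth_goutallier = wrap90(spec$fibula_azimuth),
    torsion_3d_t = wrap90(az_t - az_pta),
    torsion_3d_tf = wrap90(az_tf - az_pta),
    torsion_jakob = wrap90(spec$fibula_azimuth - spec$posterior_facet_azimuth),
    torsion_goutallier = wrap90(spec$fibula_azimuth - spec$posterior_facet_azimuth))
}

truth_for_method <- function(gt, method) {
  switch(method,
         "3D-T" = gt$torsion_3d_t,
         "3D-TF" = gt$torsion_3d_tf,
         "jakob" = gt$torsion_jakob,
         "goutallier" = gt$torsion_goutallier,
         stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

#' Ground-truth (and optionally measured) torsion table for phantom specs
#'
#' One row per spec and method with the construction ground truth; with
#' `measure = TRUE` the full pipeline is run on each generated phantom and
#' the measured angle and recovery error are added.
#'
#' @param specs list of [phantom_spec()] objects.
#' @param methods subset of `c("3D-T", "3D-TF", "jakob", "goutallier")`.
#' @param measure run the measurement pipeline.
#' @param seed integer seed threaded to the pipeline.
#' @return A data frame with columns `phantom`, `method`, `true_deg` and,
#'   when measured, `measured_deg` and `error_deg`.
#' @export
ground_truth_table <- function(specs, methods = c("3D-T", "3D-TF", "jakob", "goutallier"),
                               measure = FALSE, seed = 1) {
  if (length(specs) == 0) stop("ground_truth_table: empty spec list", call. = FALSE)
  if (length(methods) == 0) stop("ground_truth_table: empty methods filter", call. = FALSE)
  methods <- match.arg(methods, c("3D-T", "3D-TF", "jakob", "goutallier"),
                       several.ok = TRUE)
  rows <- list()
  for (i in seq_along(specs)) {
    ph <- generate_phantom(specs[[i]])
    measured <- if (measure) {
      res <- measure_torsion_all(ph$bones, seed = seed, methods = methods)
      vapply(res, function(r) r$angle, numeric(1))
    }
    for (m in methods) {
      row <- data.frame(phantom = i, method = m,
                        true_deg = truth_for_method(ph$ground_truth, m))
      if (measure) {
        row$measured_deg <- measured[[m]]
        row$error_deg <- abs(wrap180(row$measured_deg - row$true_deg))
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
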