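# The 3D measurement chain: reference-frame alignment, proximal tibia axis
# from the tibiofemoral contact areas, distal tibia joint plane, distal
# metaphyseal slab, distal tibia axis, anatomical shaft axis, and the
# projected torsion angle.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^\\[", msg)) stop(msg, call. = FALSE)
    stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
  })
}

transform_mesh <- function(mesh, R, t, mirror_x = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (mirror_x) {
    v[, 1] <- -v[, 1]
    f <- f[, c(1, 3, 2)]
  }
  v <- sweep(v %*% t(R), 2, t, `+`)
  structure(list(vertices = v, faces = f, name = mesh$name), class = "surface_mesh")
}

transform_points <- function(p, R, t, mirror_x = FALSE) {
  if (is.null(dim(p))) p <- matrix(p, 1, 3)
  if (mirror_x) p[, 1] <- -p[, 1]
  sweep(p %*% t(R), 2, t, `+`)
}

#' Align a bone set to the measurement reference frame
#'
#' Maps the mechanical axis of the tibia -- the line from the knee centre
#' to the ankle centre (the ankle centre defaults to the centroid of the
#' nine distal articular landmarks) -- onto the +y axis with +y proximal
#' and the ankle centre at the origin, then rotates about y until the
#' anterior reference point lies in the y-z plane with z > 0 (the
#' "patella facing anteriorly" pose).  Left-side inputs are mirrored
#' (x to -x) before alignment so +x is lateral for both sides and left
#' and right torsion values are directly comparable.
#'
#' @param bones a [bone_set()].
#' @return List with `bones` (the aligned [bone_set()]) and `frame`, a
#'   `reference_frame` recording `rotation`, `translation` and
#'   `side_mirrored` (the map is `x' = R (mirror(x)) + t`).
#' @export
align_to_reference <- function(bones) {
  stopifnot(inherits(bones, "bone_set"))
  lm <- bones$landmarks
  mirrored <- lm$side == "left"
  mir <- function(p) { if (mirrored) p[1] <- -p[1]; p }
  knee <- mir(lm$knee_center)
  ankle <- mir(lm$ankle_center)
  mech <- knee - ankle
  if (vnorm(mech) < 1) {
    stop("alignment: knee centre and ankle centre coincide (degenerate mechanical axis)",
         call. = FALSE)
  }
  R1 <- rotation_between(unit3(mech), c(0, 1, 0))
  a1 <- as.vector(R1 %*% (mir(lm$anterior_ref) - ankle))
  r <- sqrt(a1[1]^2 + a1[3]^2)
  if (r < 1e-9) {
    stop("alignment: anterior reference point lies on the mechanical axis", call. = FALSE)
  }
  th <- atan2(-a1[1], a1[3])
  R <- rotation_about(c(0, 1, 0), th) %*% R1
  t <- as.vector(-R %*% ankle)
  tf_mesh <- function(m) if (is.null(m)) NULL else transform_mesh(m, R, t, mirrored)
  lm2 <- landmark_set(
    distal_articular = transform_points(lm$distal_articular, R, t, mirrored),
    plateau = transform_points(lm$plateau, R, t, mirrored),
    knee_center = as.vector(transform_points(lm$knee_center, R, t, mirrored)),
    anterior_ref = as.vector(transform_points(lm$anterior_ref, R, t, mirrored)),
    ankle_center = as.vector(transform_points(lm$ankle_center, R, t, mirrored)),
    side = "right")
  aligned <- structure(list(tibia = tf_mesh(bones$tibia), femur = tf_mesh(bones$femur),
                            fibula = tf_mesh(bones$fibula), landmarks = lm2),
                       class = "bone_set")
  frame <- structure(list(rotation = R, translation = t, side_mirrored = mirrored),
                     class = "reference_frame")
  list(bones = aligned, frame = frame)
}

#' @export
print.reference_frame <- function(x, ...) {
  cat(sprintf("<reference_frame: mirrored=%s, rotation angle %.2f deg>\n",
              x$side_mirrored,
              deg(acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)))))
  invisible(x)
}

# triangle-soup helpers used by the contact-area and slab stages
soup_sample <- function(soup, n, seed) {
  areas <- face_areas(soup$vertices, soup$faces)
  with_seed(seed, {
    fi <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
  })
  A <- soup$vertices[soup$faces[fi, 1], , drop = FALSE]
  B <- soup$vertices[soup$faces[fi, 2], , drop = FALSE]
  C <- soup$vertices[soup$faces[fi, 3], , drop = FALSE]
  A * (1 - r1) + B * (r1 * (1 - r2)) + C * (r1 * r2)
}

#' Proximal tibia axis from the tibiofemoral contact areas
#'
#' In the aligned frame: (1) the most distal `condyle_band_mm` (default
#' 25 mm) of the femur is isolated; (2) two condyles are detected by
#' 2-means clustering (k-means++ initialisation) of area-uniform surface
#' samples; (3) each condylar tip cluster (CTC) is the condyle surface
#' within `tip_band_mm` (default 1 mm) of the condyle's most distal
#' point; (4) each CTC point is mapped to the closest point on the tibial
#' surface, yielding the tibiofemoral contact areas (TFCA); (5) the
#' proximal tibia axis is the first principal component of the TFCA,
#' anchored at its centroid, with positive-x direction sign.
#' Contact-area moments are integrated exactly over the clipped triangles
#' (per-triangle quadrature), so the result is deterministic; the seed
#' only affects the clustering samples.
#'
#' @param femur,tibia aligned [surface_mesh()] objects.
#' @param seed integer seed.
#' @param config a [run_config()].
#' @return An [axis3()] with attribute `"diagnostics"` (condyle
#'   separation in mm, contact-point count).
#' @export
compute_pta <- function(femur, tibia, seed = 1, config = run_config()) {
  stopifnot(inherits(femur, "surface_mesh"), inherits(tibia, "surface_mesh"))
  ymin <- min(femur$vertices[, 2])
  band <- clip_triangles_halfspace(femur$vertices, femur$faces, c(0, 1, 0),
                                   ymin + config$condyle_band_mm)
  if (nrow(band$faces) == 0) stop("condyle detection: empty distal femoral band", call. = FALSE)
  ns <- min(config$n_samples, 4000)
  samples <- soup_sample(band, ns, seed)
  km <- kmeans2(samples, seed = seed)
  separation <- vnorm(km$centers[1, ] - km$centers[2, ])
  if (separation < 10) {
    stop(sprintf("condyle detection failure: cluster separation %.1f mm (need >= 10 mm)",
                 separation), call. = FALSE)
  }
  cent <- (band$vertices[band$faces[, 1], , drop = FALSE] +
           band$vertices[band$faces[, 2], , drop = FALSE] +
           band$vertices[band$faces[, 3], , drop = FALSE]) / 3
  d1 <- rowSums(sweep(cent, 2, km$centers[1, ])^2)
  d2 <- rowSums(sweep(cent, 2, km$centers[2, ])^2)
  lab <- ifelse(d1 <= d2, 1L, 2L)
  tfca_pts <- NULL
  tfca_w <- NULL
  for (k in 1:2) {
    fk <- band$faces[lab == k, , drop = FALSE]
    if (nrow(fk) == 0) stop("condyle detection failure: empty condyle cluster", call. = FALSE)
    vy <- band$vertices[unique(as.vector(fk)), 2]
    ctc <- clip_triangles_halfspace(band$vertices, fk, c(0, 1, 0),
                                    min(vy) + config$tip_band_mm)
    if (nrow(ctc$faces) == 0) stop("condyle detection failure: empty condylar tip cluster", call. = FALSE)
    q <- triangle_quadrature(ctc$vertices, ctc$faces)
    mapped <- closest_surface_points(point_set(q$points, q$weights), tibia)
    tfca_pts <- rbind(tfca_pts, mapped$points)
    tfca_w <- c(tfca_w, q$weights)
  }
  p <- pca_axes(point_set(tfca_pts, tfca_w))
  ax <- axis3(p$center, p$components[, 1])
  attr(ax, "diagnostics") <- list(condyle_separation_mm = separation,
                                  tfca_points = nrow(tfca_pts))
  ax
}

#' Distal tibia joint plane from the nine plafond landmarks
#'
#' Total-least-squares plane through the nine distal articular points,
#' normal oriented proximally (+y half-space).
#'
#' @param landmarks a [landmark_set()] in the aligned frame.
#' @return A [plane3()] with attribute `"rms_residual"` (mm).
#' @export
fit_dtjp <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  fit_plane(landmarks$distal_articular, ref_direction = c(0, 1, 0))
}

#' Extract the distal metaphyseal slab
#'
#' Isolates the band of tibial (and optionally fibular) surface whose
#' signed distance to the distal tibia joint plane lies in
#' `[0, thickness]` on the proximal side (the default; `side = "distal"`
#' switches to `[-thickness, 0]`).  With `method = "quadrature"` (the
#' default) the slab is returned as exact per-triangle quadrature points
#' with area weights, so downstream moments are surface integrals free of
#' sampling noise; `method = "random"` draws seeded area-uniform samples
#' at equal point density (points per mm^2) for both bones.
#'
#' @param tibia aligned [surface_mesh()].
#' @param fibula aligned [surface_mesh()] or `NULL`.
#' @param dtjp the distal tibia joint plane, normal oriented proximally.
#' @param include_fibula include the corresponding fibular band.
#' @param thickness slab thickness, mm.
#' @param side `"proximal"` or `"distal"` relative to the joint plane.
#' @param method `"quadrature"` or `"random"`.
#' @param n target number of random samples on the tibial band.
#' @param seed integer seed (random method only).
#' @return A [point_set()] with attribute `"diagnostics"` (point count and
#'   band areas in mm^2).
#' @export
extract_distal_slab <- function(tibia, fibula = NULL, dtjp, include_fibula = FALSE,
                                thickness = 10, side = c("proximal", "distal"),
                                method = c("quadrature", "random"),
                                n = 8000, seed = 1) {
  side <- match.arg(side)
  method <- match.arg(method)
  stopifnot(inherits(tibia, "surface_mesh"), inherits(dtjp, "plane3"))
  if (include_fibula && is.null(fibula)) {
    stop("distal slab: include_fibula requested but no fibula mesh supplied", call. = FALSE)
  }
  nrm <- dtjp$normal
  h0 <- sum(dtjp$point * nrm)
  rng <- if (side == "proximal") c(h0, h0 + thickness) else c(h0 - thickness, h0)
  band_of <- function(mesh) clip_triangles_slab(mesh$vertices, mesh$faces, nrm, rng[1], rng[2])
  bt <- band_of(tibia)
  area_t <- if (nrow(bt$faces)) sum(face_areas(bt$vertices, bt$faces)) else 0
  bf <- NULL; area_f <- 0
  if (include_fibula) {
    bf <- band_of(fibula)
    area_f <- if (nrow(bf$faces)) sum(face_areas(bf$vertices, bf$faces)) else 0
  }
  if (method == "quadrature") {
    qt <- triangle_quadrature(bt$vertices, bt$faces)
    pts <- qt$points; w <- qt$weights
    if (include_fibula) {
      qf <- triangle_quadrature(bf$vertices, bf$faces)
      pts <- rbind(pts, qf$points); w <- c(w, qf$weights)
    }
  } else {
    if (area_t <= 0) stop("insufficient geometry in the distal slab (empty tibial band)", call. = FALSE)
    pts <- soup_sample(bt, n, seed)
    w <- NULL
    if (include_fibula && area_f > 0) {
      nf <- max(1L, round(n * area_f / area_t))
      pts <- rbind(pts, soup_sample(bf, nf, seed + 1))
    }
  }
  if (nrow(pts) < 100) {
    stop(sprintf("insufficient geometry in the distal slab (%d points, need >= 100)", nrow(pts)),
         call. = FALSE)
  }
  out <- point_set(pts, w)
  attr(out, "diagnostics") <- list(slab_points = nrow(pts),
                                   tibia_band_area_mm2 = area_t,
                                   fibula_band_area_mm2 = if (include_fibula) area_f else NA_real_)
  out
}

#' Distal tibia axis from the metaphyseal slab
#'
#' Principal component analysis of the slab point set (weighted, when the
#' slab carries quadrature weights); the distal tibia axis is the
#' component selected by `component_index` (default the second
#' component), anchored at the slab centroid, with positive-x direction
#' sign.  When the selected component's variance is within 5% of the next
#' component's, the axis is ambiguous and a warning flag is set in the
#' diagnostics (not an error).
#'
#' @param slab a [point_set()] from [extract_distal_slab()].
#' @param component_index 1 or 2.
#' @return An [axis3()] with attribute `"diagnostics"` (variances,
#'   `ambiguous` flag).
#' @export
compute_dta <- function(slab, component_index = 2) {
  stopifnot(component_index %in% c(1, 2))
  p <- pca_axes(slab)
  vr <- p$variances
  # the axis is ambiguous when the selected component could swap with
  # either neighbouring component (variances within 5%)
  ratios <- c(if (component_index > 1) vr[component_index - 1] / vr[component_index],
              if (vr[component_index + 1] > 0) vr[component_index] / vr[component_index + 1]
              else Inf)
  ratio <- min(ratios)
  ax <- axis3(p$center, p$components[, component_index])
  attr(ax, "diagnostics") <- list(variances = vr,
                                  component_index = component_index,
                                  variance_ratio_next = ratio,
                                  ambiguous = ratio < 1.05)
  ax
}

#' Anatomical axis of the tibia from shaft cross-sections
#'
#' (1) The tibial plateau plane (TPP) is fitted to the eight plateau
#' landmarks; (2) the plane normal for the shaft sections is the first
#' principal component of the whole tibial surface (exact area-weighted
#' moments), oriented distally; (3) six parallel planes are placed at
#' 20 mm intervals starting 40 mm distal of the TPP centre; (4) each
#' plane's largest-area intersection contour contributes its area
#' centroid; (5) the anatomical axis is the total-least-squares line
#' through the six centroids, oriented proximally.
#'
#' @param tibia aligned [surface_mesh()].
#' @param landmarks a [landmark_set()] in the same frame.
#' @param seed integer seed (unused; the computation is deterministic).
#' @param config a [run_config()]; `shaft_offsets_mm` holds the section
#'   offsets.
#' @return An [axis3()] with attribute `"diagnostics"` (TPP residual,
#'   section centroids).
#' @export
compute_anatomical_axis <- function(tibia, landmarks, seed = 1, config = run_config()) {
  stopifnot(inherits(tibia, "surface_mesh"), inherits(landmarks, "landmark_set"))
  tpp <- fit_plane(landmarks$plateau, ref_direction = c(0, 1, 0))
  q <- triangle_quadrature(tibia$vertices, tibia$faces)
  p <- pca_axes(point_set(q$points, q$weights))
  dir_dist <- p$components[, 1]
  if (sum(dir_dist * (p$center - tpp$point)) < 0) dir_dist <- -dir_dist
  centroids <- matrix(0, 0, 3)
  for (off in config$shaft_offsets_mm) {
    pl <- plane3(tpp$point + off * dir_dist, dir_dist)
    cts <- slice_mesh(tibia, pl)
    if (length(cts) == 0) {
      stop(sprintf("anatomical axis coverage error: no tibial cross-section at offset %g mm",
                   off), call. = FALSE)
    }
    areas <- vapply(cts, contour_area, numeric(1))
    centroids <- rbind(centroids, contour_centroid(cts[[which.max(areas)]]))
  }
  line <- pca_axes(point_set(centroids))
  d <- line$components[, 1]
  if (sum(d * (tpp$point - line$center)) < 0) d <- -d
  ax <- axis3(line$center, d)
  attr(ax, "diagnostics") <- list(tpp_rms_residual_mm = attr(tpp, "rms_residual"),
                                  section_centroids = centroids)
  ax
}

torsion_result <- function(angle, variant, pta, dta, anatomical_axis = NULL,
                           frame = NULL, diagnostics = list()) {
  structure(list(angle = wrap180(angle), variant = variant, pta = pta, dta = dta,
                 anatomical_axis = anatomical_axis, frame = frame,
                 diagnostics = diagnostics),
            class = "torsion_result")
}

#' @export
print.torsion_result <- function(x, ...) {
  cat(sprintf("<torsion_result %s: %.2f deg (external positive)>\n", x$variant, x$angle))
  invisible(x)
}

#' Measure tibial torsion with the 3D technique
#'
#' Full measurement chain: reference alignment, proximal tibia axis from
#' the tibiofemoral contact areas, distal tibia joint plane, distal
#' metaphyseal slab (tibia only for `"3D-T"`, tibia plus fibula for
#' `"3D-TF"`), distal tibia axis, anatomical shaft axis; the torsion
#' angle is the signed angle from the proximal to the distal axis after
#' projecting both onto the plane perpendicular to the anatomical axis.
#' Both axes carry a 180-degree direction ambiguity, resolved toward the
#' smaller absolute angle, so reported torsion lies in (-90, 90].
#' External rotation of the distal segment is positive (right-hand rule
#' about the proximally-directed anatomical axis with +x lateral; left
#' sides are mirrored during alignment).
#'
#' @param bones a [bone_set()] with tibia, femur, landmarks and (for
#'   `"3D-TF"`) fibula.
#' @param variant `"3D-T"` or `"3D-TF"`.
#' @param seed integer seed.
#' @param config a [run_config()].
#' @return A `torsion_result` carrying the angle, all intermediate axes,
#'   the reference frame and per-stage diagnostics.
#' @export
measure_torsion_3d <- function(bones, variant = c("3D-T", "3D-TF"), seed = 1,
                               config = run_config()) {
  variant <- match.arg(variant)
  if (is.null(bones$femur)) {
    stop("[input] 3D measurement requires a femur mesh", call. = FALSE)
  }
  if (variant == "3D-TF" && is.null(bones$fibula)) {
    stop("[input] variant 3D-TF requires a fibula mesh", call. = FALSE)
  }
  al <- run_stage("alignment", align_to_reference(bones))
  b <- al$bones
  pta <- run_stage("proximal axis", compute_pta(b$femur, b$tibia, seed = seed, config = config))
  dtjp <- run_stage("distal joint plane", fit_dtjp(b$landmarks))
  slab <- run_stage("distal slab",
                    extract_distal_slab(b$tibia, b$fibula, dtjp,
                                        include_fibula = variant == "3D-TF",
                                        thickness = config$slab_thickness_mm,
                                        side = config$slab_side,
                                        n = config$n_samples, seed = seed))
  dta <- run_stage("distal axis", compute_dta(slab, component_index = config$dta_component))
  anat <- run_stage("anatomical axis",
                    compute_anatomical_axis(b$tibia, b$landmarks, seed = seed, config = config))
  nproj <- anat$direction  # proximally oriented
  pta_p <- run_stage("projection", project_direction(pta$direction, nproj))
  dta_p <- run_stage("projection", project_direction(dta$direction, nproj))
  # the distal axis is an axis, not a vector: resolve its 180-degree
  # ambiguity toward the smaller absolute torsion, so angles lie in (-90, 90]
  angle <- wrap90(signed_angle_about(pta_p, dta_p, nproj))
  diagnostics <- c(attr(pta, "diagnostics"),
                   list(dtjp_rms_residual_mm = attr(dtjp, "rms_residual")),
                   attr(slab, "diagnostics"),
                   attr(dta, "diagnostics")["variance_ratio_next"],
                   list(dta_ambiguous = attr(dta, "diagnostics")$ambiguous,
                        dta_component_index = config$dta_component))
  torsion_result(angle, variant, pta, dta, anatomical_axis = anat,
                 frame = al$frame, diagnostics = diagnostics)
}

#' Measure torsion with several methods sharing one alignment
#'
#' Runs the requested subset of the four methods on one bone set,
#' computing the shared stages (alignment, joint plane, proximal contact
#' axis, anatomical axis) once.
#'
#' @param bones a [bone_set()].
#' @param seed integer seed.
#' @param methods subset of `c("3D-T", "3D-TF", "jakob", "goutallier")`.
#' @param config a [run_config()].
#' @return Named list of `torsion_result` objects.
#' @export
measure_torsion_all <- function(bones, seed = 1,
                                methods = c("3D-T", "3D-TF", "jakob", "goutallier"),
                                config = run_config()) {
  methods <- match.arg(methods, c("3D-T", "3D-TF", "jakob", "goutallier"),
                       several.ok = TRUE)
  al <- run_stage("alignment", align_to_reference(bones))
  b <- al$bones
  out <- list()
  need_3d <- any(methods %in% c("3D-T", "3D-TF"))
  dtjp <- run_stage("distal joint plane", fit_dtjp(b$landmarks))
  if (need_3d) {
    if (is.null(b$femur)) stop("[input] 3D measurement requires a femur mesh", call. = FALSE)
    pta <- run_stage("proximal axis", compute_pta(b$femur, b$tibia, seed = seed, config = config))
    anat <- run_stage("anatomical axis",
                      compute_anatomical_axis(b$tibia, b$landmarks, seed = seed, config = config))
    for (variant in intersect(methods, c("3D-T", "3D-TF"))) {
      if (variant == "3D-TF" && is.null(b$fibula)) {
        stop("[input] variant 3D-TF requires a fibula mesh", call. = FALSE)
      }
      slab <- run_stage("distal slab",
                        extract_distal_slab(b$tibia, b$fibula, dtjp,
                                            include_fibula = variant == "3D-TF",
                                            thickness = config$slab_thickness_mm,
                                            side = config$slab_side,
                                            n = config$n_samples, seed = seed))
      dta <- run_stage("distal axis", compute_dta(slab, component_index = config$dta_component))
      nproj <- anat$direction
      angle <- wrap90(signed_angle_about(project_direction(pta$direction, nproj),
                                         project_direction(dta$direction, nproj), nproj))
      out[[variant]] <- torsion_result(
        angle, variant, pta, dta, anatomical_axis = anat, frame = al$frame,
        diagnostics = c(attr(pta, "diagnostics"), attr(slab, "diagnostics"),
                        list(dta_ambiguous = attr(dta, "diagnostics")$ambiguous)))
    }
  }
  for (m in intersect(methods, c("jakob", "goutallier"))) {
    out[[m]] <- measure_torsion_2d_aligned(b, al$frame, dtjp, method = m, config = config)
  }
  out[methods]
}
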