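test_that("alignment maps the mechanical axis to +y and the anterior point to +z", {
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  al <- align_to_reference(ph$bones)
  # phantom already in reference pose: identity transform
  ang <- acos(pmin((sum(diag(al$frame$rotation)) - 1) / 2, 1)) * 180 / pi
  expect_lt(ang, 1e-7)
  expect_false(al$frame$side_mirrored)

  withr::with_seed(31, {
    R <- random_rotation()
    tr <- stats::runif(3, -200, 200)
  })
  al2 <- align_to_reference(transform_bone_set(ph$bones, R, tr))
  lm2 <- al2$bones$landmarks
  mech <- lm2$knee_center - lm2$ankle_center
  expect_equal(mech / sqrt(sum(mech^2)), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(abs(lm2$anterior_ref[1]), 1e-9)
  expect_gt(lm2$anterior_ref[3], 0)
  # aligned meshes coincide with the in-pose originals
  expect_lt(max(abs(al2$bones$tibia$vertices - al$bones$tibia$vertices)), 1e-6)
})

test_that("left-side phantoms mirror onto their right-side twins", {
  phR <- cached_phantom("t25", phantom_spec(torsion = 25))
  phL <- cached_phantom("t25L", phantom_spec(torsion = 25, side = "left"))
  alR <- align_to_reference(phR$bones)
  alL <- align_to_reference(phL$bones)
  expect_true(alL$frame$side_mirrored)
  expect_lt(max(abs(alL$bones$tibia$vertices - alR$bones$tibia$vertices)), 1e-6)
  expect_lt(max(abs(alL$bones$femur$vertices - alR$bones$femur$vertices)), 1e-6)
})

test_that("degenerate alignment landmarks are rejected", {
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  lm <- ph$bones$landmarks
  bad <- landmark_set(lm$distal_articular, lm$plateau,
                      knee_center = lm$ankle_center + c(0, 0.5, 0),
                      anterior_ref = lm$anterior_ref,
                      ankle_center = lm$ankle_center, side = "right")
  bones <- bone_set(ph$bones$tibia, ph$bones$femur, ph$bones$fibula, bad,
                    check_proximity = FALSE)
  expect_error(align_to_reference(bones), "degenerate mechanical axis")
})

test_that("the proximal tibia axis tracks the condylar contact line", {
  al0 <- align_to_reference(cached_phantom("t0", phantom_spec(torsion = 0))$bones)$bones
  pta0 <- compute_pta(al0$femur, al0$tibia, seed = 1)
  expect_lt(angle_err(tibtor:::azimuth_of(pta0$direction), 0), 1)

  ph15 <- cached_phantom("caz15", phantom_spec(condyle_azimuth = 15, fibula_azimuth = 15,
                                               distal_major_azimuth = -75))
  al15 <- align_to_reference(ph15$bones)$bones
  pta15 <- compute_pta(al15$femur, al15$tibia, seed = 1)
  expect_lt(angle_err(tibtor:::azimuth_of(pta15$direction), 15), 1)

  # translating the femur slightly must not change the contact azimuth
  fem_shift <- surface_mesh(sweep(al0$femur$vertices, 2, c(0, 0, 2), `+`),
                            al0$femur$faces, "femur", clean = FALSE)
  pta_shift <- compute_pta(fem_shift, al0$tibia, seed = 1)
  expect_lt(angle_err(tibtor:::azimuth_of(pta_shift$direction),
                      tibtor:::azimuth_of(pta0$direction)), 0.5)

  d <- attr(pta0, "diagnostics")
  expect_gt(d$condyle_separation_mm, 10)
  expect_gt(d$tfca_points, 0)
})

test_that("the distal joint plane fit matches the plafond construction", {
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  lm <- align_to_reference(ph$bones)$bones$landmarks
  dtjp <- fit_dtjp(lm)
  expect_equal(dtjp$normal, c(0, 1, 0), tolerance = 1e-9)
  # aligned frame: the ankle centre (plafond centroid) sits at the origin
  expect_equal(dtjp$point[2], 0, tolerance = 1e-9)

  # plafond tilted 5 degrees about x: normal follows within 0.1 degrees
  Rx <- tibtor:::rotation_about(c(1, 0, 0), 5 * pi / 180)
  tilted <- landmark_set(lm$distal_articular %*% t(Rx), lm$plateau, lm$knee_center,
                         lm$anterior_ref, side = "right")
  n2 <- fit_dtjp(tilted)$normal
  expect_lt(acos(min(sum(n2 * (Rx %*% c(0, 1, 0))), 1)) * 180 / pi, 0.1)

  # noisy plafond points: RMS residual reported and bounded
  withr::with_seed(8, noisy <- lm$distal_articular + matrix(stats::rnorm(27, sd = 0.3), 9))
  dn <- fit_dtjp(landmark_set(noisy, lm$plateau, lm$knee_center, lm$anterior_ref,
                              side = "right"))
  expect_lt(attr(dn, "rms_residual"), 1)
})

test_that("the distal slab respects its band contract and density", {
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  b <- align_to_reference(ph$bones)$bones
  dtjp <- fit_dtjp(b$landmarks)

  slab_r <- extract_distal_slab(b$tibia, b$fibula, dtjp, include_fibula = TRUE,
                                method = "random", n = 4000, seed = 2)
  d <- as.vector(sweep(slab_r$points, 2, dtjp$point) %*% dtjp$normal)
  expect_true(all(d >= -1e-6 & d <= 10 + 1e-6))

  # fibula share of random samples matches the band area ratio (binomial bound)
  diag_q <- attr(extract_distal_slab(b$tibia, b$fibula, dtjp, include_fibula = TRUE),
                 "diagnostics")
  frac <- diag_q$fibula_band_area_mm2 /
    (diag_q$fibula_band_area_mm2 + diag_q$tibia_band_area_mm2)
  n_fib <- sum(slab_r$points[, 1] > 20)  # fibula band sits laterally on this phantom
  n_tot <- nrow(slab_r$points)
  expect_lt(abs(n_fib / n_tot - frac), 4 * sqrt(frac * (1 - frac) / n_tot) + 0.01)

  # error paths
  expect_error(extract_distal_slab(b$tibia, NULL, dtjp, include_fibula = TRUE),
               "fibula")
  coarse <- cylinder_mesh(r = 10, n_theta = 6, n_y = 2)
  expect_error(extract_distal_slab(coarse, NULL, plane3(c(0, 0, 0), c(0, 1, 0)),
                                   thickness = 0.5),
               "insufficient geometry")
})

test_that("the distal axis is the chosen principal component of the slab", {
  # analytic elliptical band, semi-axes 25 x 18, height 10: second
  # component is the minor axis (azimuth 90 for major at 0)
  t <- seq(0, 2 * pi, length.out = 721)[-721]
  wt <- rep(sqrt((25 * sin(t))^2 + (18 * cos(t))^2), 3)
  band <- function(az_deg) {
    a <- az_deg * pi / 180
    u <- c(cos(a), -sin(a)); w <- c(-sin(a), -cos(a))
    xy <- cbind(25 * cos(t) * u[1] + 18 * sin(t) * w[1],
                25 * cos(t) * u[2] + 18 * sin(t) * w[2])
    pts <- rbind(cbind(xy[, 1], -5, xy[, 2]),
                 cbind(xy[, 1], 0, xy[, 2]),
                 cbind(xy[, 1], 5, xy[, 2]))
    point_set(pts, wt)
  }
  d0 <- compute_dta(band(0), component_index = 2)
  expect_lt(angle_err(tibtor:::azimuth_of(d0$direction), 90), 1)
  d30 <- compute_dta(band(30), component_index = 2)
  expect_lt(angle_err(tibtor:::azimuth_of(d30$direction), 120), 1)
  expect_false(attr(d0, "diagnostics")$ambiguous)

  # first component of a two-blob tibia+fibula slab joins the blob centroids
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  b <- align_to_reference(ph$bones)$bones
  dtjp <- fit_dtjp(b$landmarks)
  slab <- extract_distal_slab(b$tibia, b$fibula, dtjp, include_fibula = TRUE)
  d1 <- compute_dta(slab, component_index = 1)
  # oracle: direct covariance eigen-decomposition of the same weighted points
  cv <- stats::cov.wt(slab$points, slab$weights, method = "ML")
  first <- eigen(cv$cov, symmetric = TRUE)$vectors[, 1]
  expect_lt(angle_err(tibtor:::azimuth_of(d1$direction), tibtor:::azimuth_of(first)), 1e-6)
  expect_lt(angle_err(tibtor:::azimuth_of(d1$direction), 25), 2)
})

test_that("a near-isotropic slab raises the ambiguity flag, not an error", {
  ph <- cached_phantom("iso", phantom_spec(torsion = 10, distal_semi_axes = c(18.3, 18)))
  b <- align_to_reference(ph$bones)$bones
  slab <- extract_distal_slab(b$tibia, NULL, fit_dtjp(b$landmarks))
  d <- compute_dta(slab, component_index = 2)
  expect_true(attr(d, "diagnostics")$ambiguous)
  expect_lt(attr(d, "diagnostics")$variance_ratio_next, 1.05)
})

test_that("the anatomical axis follows the shaft and reports coverage failures", {
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  b <- align_to_reference(ph$bones)$bones
  ax <- compute_anatomical_axis(b$tibia, b$landmarks)
  expect_lt(acos(min(sum(ax$direction * c(0, 1, 0)), 1)) * 180 / pi, 0.2)

  # tilted phantom: axis follows the tilt
  ph3 <- cached_phantom("tilt3", phantom_spec(torsion = 25, shaft_tilt = 3))
  ax3 <- compute_anatomical_axis(ph3$bones$tibia, ph3$bones$landmarks)
  Rt <- tibtor:::rotation_about(c(1, 0, 0), 3 * pi / 180)
  expect_lt(acos(min(sum(ax3$direction * (Rt %*% c(0, 1, 0))), 1)) * 180 / pi, 0.3)

  # shaft truncated 120 mm below the plateau: the 140 mm section is empty
  y_top <- max(b$tibia$vertices[, 2])
  keep <- tibtor:::clip_triangles_halfspace(b$tibia$vertices, b$tibia$faces,
                                            c(0, -1, 0), -(y_top - 130))
  trunc <- surface_mesh(keep$vertices, keep$faces, "tibia")
  expect_error(compute_anatomical_axis(trunc, b$landmarks), "140")
})

test_that("3D torsion recovers the construction truth for both variants", {
  ph <- cached_phantom("t30", phantom_spec(torsion = 30))
  r_t <- measure_torsion_3d(ph$bones, "3D-T", seed = 1)
  r_tf <- measure_torsion_3d(ph$bones, "3D-TF", seed = 1)
  expect_lt(angle_err(r_t$angle, ph$ground_truth$torsion_3d_t), 2)
  expect_lt(angle_err(r_tf$angle, ph$ground_truth$torsion_3d_tf), 2)
  expect_gt(r_t$diagnostics$condyle_separation_mm, 10)
  expect_false(r_t$diagnostics$dta_ambiguous)
  expect_s3_class(r_t$pta, "axis3")
  expect_s3_class(r_t$anatomical_axis, "axis3")
})

test_that("3D torsion is invariant under joint rigid transforms and mirroring", {
  ph <- cached_phantom("t30", phantom_spec(torsion = 30))
  base <- measure_torsion_3d(ph$bones, "3D-T", seed = 1)$angle
  withr::with_seed(17, {
    for (i in 1:2) {
      moved <- transform_bone_set(ph$bones, random_rotation(), stats::runif(3, -100, 100))
      expect_lt(abs(measure_torsion_3d(moved, "3D-T", seed = 1)$angle - base), 0.1)
    }
  })
  phL <- cached_phantom("t30L", phantom_spec(torsion = 30, side = "left"))
  expect_lt(abs(measure_torsion_3d(phL$bones, "3D-T", seed = 1)$angle - base), 0.1)
})

test_that("different seeds give near-identical torsion (sampling noise only)", {
  ph <- cached_phantom("t30", phantom_spec(torsion = 30))
  a1 <- measure_torsion_3d(ph$bones, "3D-T", seed = 1)$angle
  a2 <- measure_torsion_3d(ph$bones, "3D-T", seed = 2)$angle
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("missing bones raise stage-named input errors", {
  ph <- cached_phantom("t30", phantom_spec(torsion = 30))
  no_fib <- bone_set(ph$bones$tibia, ph$bones$femur, NULL, ph$bones$landmarks,
                     check_proximity = FALSE)
  expect_error(measure_torsion_3d(no_fib, "3D-TF"), "fibula")
  no_fem <- bone_set(ph$bones$tibia, NULL, ph$bones$fibula, ph$bones$landmarks,
                     check_proximity = FALSE)
  expect_error(measure_torsion_3d(no_fem, "3D-T"), "femur")
})
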