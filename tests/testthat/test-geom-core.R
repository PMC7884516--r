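test_that("pca_axes matches closed-form covariance of a box corner set", {
  corners <- as.matrix(expand.grid(x = c(-10, 10), y = c(-5, 5), z = c(-2, 2)))
  p <- pca_axes(corners)
  expect_equal(p$center, c(0, 0, 0))
  expect_equal(p$variances, c(100, 25, 4))
  expect_equal(abs(p$components), diag(3), tolerance = 1e-12)
  # deterministic sign convention: components point into +x / +y / +z
  expect_true(all(diag(p$components) > 0))
})

test_that("pca_axes flags collinear data and is rigidly equivariant", {
  seg <- cbind(seq(0, 10, length.out = 25), 0, 0)
  p <- pca_axes(seg)
  expect_equal(p$components[, 1], c(1, 0, 0))
  expect_lt(p$variances[2] + p$variances[3], 1e-20)

  withr::with_seed(7, {
    pts <- matrix(stats::rnorm(90), ncol = 3) %*% diag(c(3, 2, 1))
    R <- random_rotation()
  })
  p0 <- pca_axes(pts)
  p1 <- pca_axes(pts %*% t(R))
  expect_equal(p1$variances, p0$variances, tolerance = 1e-9)
  rotated <- R %*% p0$components
  for (j in 1:3) {
    expect_equal(abs(sum(rotated[, j] * p1$components[, j])), 1, tolerance = 1e-9)
  }
})

test_that("fit_plane is the total-least-squares optimum", {
  # exact plane
  withr::with_seed(1, pts <- cbind(stats::rnorm(9, sd = 5), stats::rnorm(9, sd = 5), 0))
  pl <- fit_plane(pts, ref_direction = c(0, 0, 1))
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(attr(pl, "rms_residual"), 0, tolerance = 1e-9)

  # symmetric residuals: square corners alternating z = +/-1
  sq <- rbind(c(2, 2, 1), c(-2, 2, -1), c(-2, -2, 1), c(2, -2, -1))
  pl2 <- fit_plane(sq, ref_direction = c(0, 0, 1))
  expect_equal(pl2$normal, c(0, 0, 1), tolerance = 1e-12)

  # tilted plane plus seeded noise: recovered within 0.5 degrees
  withr::with_seed(42, {
    x <- stats::runif(9, -20, 20); y <- stats::runif(9, -20, 20)
    z <- 0.1 * x + 5 + stats::rnorm(9, sd = 0.1)
  })
  pl3 <- fit_plane(cbind(x, y, z), ref_direction = c(0, 0, 1))
  true_n <- c(-0.1, 0, 1) / sqrt(1.01)
  ang <- acos(min(sum(pl3$normal * true_n), 1)) * 180 / pi
  expect_lt(ang, 0.5)

  # residual optimality against 1000 random candidate planes
  rss <- function(pts, pl) {
    d <- as.vector(sweep(pts, 2, pl$point) %*% pl$normal)
    sum(d^2)
  }
  pts3 <- cbind(x, y, z)
  best <- rss(pts3, pl3)
  withr::with_seed(3, {
    for (i in 1:1000) {
      n <- stats::rnorm(3); n <- n / sqrt(sum(n * n))
      cand <- plane3(colMeans(pts3) + stats::rnorm(3, sd = 0.05), n)
      expect_gte(rss(pts3, cand), best - 1e-9)
    }
  })

  expect_error(fit_plane(cbind(1:5, 0, 0)), "collinear")
})

test_that("kmeans2 separates blobs, matches brute force, and is seed-stable", {
  withr::with_seed(5, {
    b1 <- matrix(stats::rnorm(300, sd = 2), ncol = 3)
    b2 <- sweep(matrix(stats::rnorm(300, sd = 2), ncol = 3), 2, c(50, 0, 0), `+`)
  })
  km <- kmeans2(rbind(b1, b2), seed = 1)
  expect_equal(length(unique(km$labels[1:100])), 1)
  expect_equal(length(unique(km$labels[101:200])), 1)
  expect_lt(sqrt(sum((km$centers[1, ] - colMeans(b2))^2)), 1)  # cluster 1 has larger x
  expect_lt(sqrt(sum((km$centers[2, ] - colMeans(b1))^2)), 1)

  # frozen 4-point case: optimal partition {1,2} {3,4}, WCSS = 1.0
  four <- cbind(c(0, 1, 10, 11), 0, 0)
  km4 <- kmeans2(four, seed = 3)
  expect_equal(km4$wcss, 1.0)
  expect_equal(km4$labels[1], km4$labels[2])
  expect_equal(km4$labels[3], km4$labels[4])

  # exact match to brute-force enumeration of all 2-partitions on <= 8 points
  brute_wcss <- function(x) {
    n <- nrow(x)
    best <- Inf
    for (mask in 1:(2^(n - 1) - 1)) {
      g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      if (!any(g) || all(g)) next
      w <- sum(sweep(x[g, , drop = FALSE], 2, colMeans(x[g, , drop = FALSE]))^2) +
        sum(sweep(x[!g, , drop = FALSE], 2, colMeans(x[!g, , drop = FALSE]))^2)
      best <- min(best, w)
    }
    best
  }
  withr::with_seed(9, {
    for (rep in 1:10) {
      x <- matrix(stats::rnorm(3 * sample(4:8, 1)), ncol = 3)
      expect_equal(kmeans2(x, seed = rep, nstart = 20)$wcss, brute_wcss(x), tolerance = 1e-9)
    }
  })

  # determinism for separated data: any seed gives the same partition
  km_a <- kmeans2(rbind(b1, b2), seed = 10)
  km_b <- kmeans2(rbind(b1, b2), seed = 99)
  expect_identical(km_a$labels, km_b$labels)

  expect_error(kmeans2(matrix(1, 5, 3), seed = 1), "identical")
})

test_that("fit_circle_2d recovers exact circles, circumcircles and arcs", {
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- cbind(3 + 7 * cos(t), -2 + 7 * sin(t))
  f <- fit_circle_2d(pts)
  expect_equal(f$center, c(3, -2), tolerance = 1e-9)
  expect_equal(f$radius, 7, tolerance = 1e-9)

  f3 <- fit_circle_2d(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(f3$center, c(1, 0), tolerance = 1e-9)
  expect_equal(f3$radius, 1, tolerance = 1e-9)

  # half-circle arc: full coverage must not be required
  ta <- seq(0, pi, length.out = 20)
  fa <- fit_circle_2d(cbind(5 + 4 * cos(ta), 1 + 4 * sin(ta)))
  expect_equal(fa$center, c(5, 1), tolerance = 1e-6)
  expect_equal(fa$radius, 4, tolerance = 1e-6)

  expect_error(fit_circle_2d(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("slice_mesh recovers analytic cross-sections and converges under refinement", {
  areas <- sapply(c(48, 96), function(n) {
    cyl <- cylinder_mesh(r = 10, n_theta = n)
    cts <- slice_mesh(cyl, plane3(c(0, 3.1, 0), c(0, 1, 0)))
    expect_length(cts, 1)
    tibtor:::contour_area(cts[[1]])
  })
  true_area <- 100 * pi
  expect_lt(abs(areas[2] - true_area) / true_area, 0.005)
  # refinement reduces the tessellation error
  expect_lt(abs(areas[2] - true_area), abs(areas[1] - true_area))

  # plane missing the mesh entirely: empty result, not an error
  expect_length(slice_mesh(cylinder_mesh(), plane3(c(0, 500, 0), c(0, 1, 0))), 0)

  # phantom at a level with tibia shaft + separate malleolar block: 2 contours
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  lev <- -ph$spec$shaft_length - 1
  cts <- slice_mesh(ph$bones$tibia, plane3(c(0, lev, 0), c(0, 1, 0)))
  expect_length(cts, 1)  # only the malleolar block below the plafond
  cts2 <- slice_mesh(ph$bones$tibia, plane3(c(0, -50, 0), c(0, 1, 0)))
  expect_length(cts2, 1)  # single shaft section
})

test_that("contour orientation and centroid follow the shoelace formula", {
  cyl <- cylinder_mesh(r = 5)
  ct <- slice_mesh(cyl, plane3(c(0, 1.2, 0), c(0, 1, 0)))[[1]]
  expect_true(tibtor:::polygon_area(ct$polygon) > 0)  # CCW about the normal

  shoelace_centroid <- function(p) {
    n <- nrow(p); i2 <- c(2:n, 1)
    cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
    a <- sum(cr) / 2
    c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
  }
  # L-shaped hexagon in an axial plane (y = 0); plane coords are (x, -z)
  L2 <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  pl <- plane3(c(0, 0, 0), c(0, 1, 0))
  ct_L <- tibtor:::planar_contour(pl, L2)
  cen <- contour_centroid(ct_L)
  oracle <- shoelace_centroid(L2)
  # 2x2 square minus its top-right unit square: centroid (5/6, 5/6)
  expect_equal(oracle, c(5 / 6, 5 / 6), tolerance = 1e-12)
  expect_equal(cen, c(oracle[1], 0, -oracle[2]), tolerance = 1e-12)

  # translation equivariance
  ct_T <- tibtor:::planar_contour(plane3(c(3, 4, 5), c(0, 1, 0)), L2)
  expect_equal(contour_centroid(ct_T) - contour_centroid(ct_L), c(3, 4, 5))

  expect_error(contour_centroid(tibtor:::planar_contour(pl, L2, closed = FALSE)), "closed")
})

test_that("closest_surface_points equals exhaustive face search", {
  ph <- cached_phantom("t25", phantom_spec(torsion = 25))
  mesh <- ph$bones$femur
  withr::with_seed(21, {
    q <- cbind(stats::runif(50, -60, 60), stats::runif(50, -20, 60), stats::runif(50, -60, 60))
  })
  got <- closest_surface_points(q, mesh)$points
  # oracle: per-face distances over every face, no pre-filtering
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  for (i in seq_len(nrow(q))) {
    res <- tibtor:::point_triangles_closest(q[i, ], A, B, C)
    expect_lt(sqrt(sum((got[i, ] - res$points[which.min(res$dist2), ])^2)), 1e-9)
  }

  # analytic cases: orthogonal projection inside a face; edge region outside
  tri <- surface_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 1)),
                      rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 2), c(2, 3, 4)), clean = FALSE)
  inside <- closest_surface_points(matrix(c(2, 3, 5), 1), tri)$points
  expect_equal(as.vector(inside), c(2, 3, 0), tolerance = 1e-12)
  beyond <- closest_surface_points(matrix(c(-4, 3, 2), 1), tri)$points
  expect_equal(as.vector(beyond), c(0, 3, 0), tolerance = 1e-12)
})

test_that("sample_surface is area-uniform and seed-deterministic", {
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 3, 4), c(3, 2, 1), c(4, 3, 1)), clean = FALSE)
  s <- sample_surface(sq, 10000, seed = 4)
  # two equal-area triangles: binomial 4-sd bound (per original orientation pair)
  upper <- sum(s$points[, 2] > s$points[, 1])  # above the diagonal
  expect_gt(upper, 5000 - 2 * 200)
  expect_lt(upper, 5000 + 2 * 200)

  # dominant face receives its area share
  big <- surface_mesh(rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 1), c(1, 0, 1), c(0, 1, 1)),
                      rbind(c(1, 2, 3), c(4, 5, 6), c(3, 2, 1), c(6, 5, 4)), clean = FALSE)
  sb <- sample_surface(big, 10000, seed = 9)
  expect_gte(sum(sb$points[, 3] < 0.5), 9700)

  expect_identical(sample_surface(sq, 500, seed = 7)$points,
                   sample_surface(sq, 500, seed = 7)$points)
  expect_false(identical(sample_surface(sq, 500, seed = 7)$points,
                         sample_surface(sq, 500, seed = 8)$points))
})

test_that("projection and signed angles obey their contracts", {
  expect_equal(project_direction(c(1, 0, 0), c(0, 1, 0)), c(1, 0, 0))
  expect_equal(project_direction(c(1, 1, 0), c(0, 1, 0)), c(1, 0, 0))
  v <- project_direction(c(0.3, -0.8, 0.5), c(0, 1, 0))
  expect_equal(project_direction(v, c(0, 1, 0)), v)  # idempotent
  expect_lt(abs(sum(v * c(0, 1, 0))), 1e-12)
  expect_error(project_direction(c(0, 2, 0), c(0, 1, 0)), "parallel")

  expect_equal(signed_angle_about(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)), 0)
  # right-hand rule
  expect_equal(signed_angle_about(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)), 90)
  withr::with_seed(13, {
    for (i in 1:100) {
      ax <- c(0, 1, 0)
      a <- project_direction(stats::rnorm(3), ax)
      b <- project_direction(stats::rnorm(3), ax)
      cc <- project_direction(stats::rnorm(3), ax)
      expect_equal(signed_angle_about(a, b, ax), -signed_angle_about(b, a, ax),
                   tolerance = 1e-9)
      s <- signed_angle_about(a, b, ax) + signed_angle_about(b, cc, ax) -
        signed_angle_about(a, cc, ax)
      expect_lt(min(abs(c(s, s - 360, s + 360))), 1e-9)
    }
  })
})
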