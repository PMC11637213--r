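test_that("point cloud and transform constructors enforce their invariants", {
  expect_error(point_cloud(matrix(c(1, 2, Inf), 1, 3)), "finite")
  expect_error(point_cloud(diag(3), normals = matrix(c(2, 0, 0), 1, 3)),
               "one row per point")
  expect_error(point_cloud(matrix(0, 1, 3), normals = matrix(c(2, 0, 0), 1, 3)),
               "unit length")
  expect_error(rigid_transform(matrix(1, 3, 3)), "proper orthogonal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper orthogonal")
})

test_that("apply_transform maps points as R p + t and composes correctly", {
  cl <- point_cloud(matrix(c(1, 0, 0), 1, 3))
  expect_equal(apply_transform(cl, rigid_transform())$points, cl$points)
  half_turn <- rigid_transform(rotation_about_axis(c(0, 0, 1), 180))
  expect_equal(apply_transform(cl, half_turn)$points,
               matrix(c(-1, 0, 0), 1, 3), tolerance = 1e-12)
  cl2 <- random_cloud(50, seed = 2)
  t1 <- random_rigid(3); t2 <- random_rigid(4)
  seq_applied <- apply_transform(apply_transform(cl2, t1), t2)
  composed <- apply_transform(cl2, compose_transform(t2, t1))
  expect_equal(seq_applied$points, composed$points, tolerance = 1e-12)
  # inverse round-trips
  back <- apply_transform(apply_transform(cl2, t1), invert_transform(t1))
  expect_equal(back$points, cl2$points, tolerance = 1e-10)
})

test_that("rigid transforms preserve pairwise distances", {
  for (s in 1:5) {
    cl <- random_cloud(40, seed = s, scale = 5)
    tf <- random_rigid(s + 10, angle = 170, trans = 20)
    d0 <- dist(cl$points)
    d1 <- dist(apply_transform(cl, tf)$points)
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("knn_search matches exhaustive search and breaks ties low", {
  cl <- random_cloud(100, seed = 7)
  q <- c(0.1, -0.2, 0.3)
  d <- sqrt(colSums((t(cl$points) - q)^2))
  for (k in c(1, 5, 100)) {
    expect_equal(knn_search(cl, q, k), order(d)[seq_len(k)])
  }
  # query equal to a target point
  expect_equal(knn_search(cl, cl$points[42, ], 1), 42L)
  # exact tie resolves to the lower index
  tie <- point_cloud(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 5, 0)))
  expect_equal(knn_search(tie, c(0, 0, 0), 2), c(1L, 2L))
  expect_error(knn_search(tie, c(0, 0, 0), 4), "exceeds")
})

test_that("estimate_normals recovers analytic normals", {
  # planar grid: all normals are +-z
  g <- as.matrix(expand.grid(x = 1:8, y = 1:8))
  plane <- point_cloud(cbind(g, 0))
  n <- estimate_normals(plane, k = 8)$normals
  expect_equal(abs(n[, 3]), rep(1, 64), tolerance = 1e-9)
  # unit sphere: normals align with the radial direction
  sph <- with_seed_test(11, {
    u <- matrix(rnorm(6000), 2000, 3)
    point_cloud(u / sqrt(rowSums(u^2)))
  })
  ns <- estimate_normals(sph, k = 10)$normals
  ca <- abs(rowSums(ns * sph$points))
  ang <- acos(pmin(1, ca)) * 180 / pi
  expect_gte(mean(ang < 5), 0.99)
  # outward orientation: radial dot product positive
  expect_gte(mean(rowSums(ns * sph$points) > 0), 0.99)
  # coincident points flag a degenerate neighbourhood
  co <- point_cloud(matrix(1, 5, 3) + rbind(0, 0, 0, 0, c(5, 5, 5)))
  expect_error(estimate_normals(co, k = 3), "degenerate neighbourhood")
})

test_that("pca_frame canonicalises axes and detects degeneracy", {
  cl <- with_seed_test(5, point_cloud(cbind(rnorm(500, sd = 3),
                                            rnorm(500, sd = 2),
                                            rnorm(500, sd = 1))))
  fr <- pca_frame(cl)
  expect_equal(fr$origin, colMeans(cl$points))
  expect_gt(abs(fr$axes[1, 1]), 0.99)
  expect_gt(abs(fr$axes[2, 2]), 0.99)
  expect_gte(fr$axes[1, 1], 0)   # sign canonicalised
  expect_gte(fr$axes[2, 2], 0)
  # right-handed triad
  expect_equal(phmsr:::cross3(fr$axes[1, ], fr$axes[2, ]), fr$axes[3, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # translation moves the origin, not the axes
  sh <- apply_transform(cl, rigid_transform(translation = c(3, -1, 2)))
  fr2 <- pca_frame(sh)
  expect_equal(fr2$origin, fr$origin + c(3, -1, 2), tolerance = 1e-9)
  expect_equal(fr2$axes, fr$axes, tolerance = 1e-9)
  # collinear input
  line <- point_cloud(cbind(1:10, 2 * (1:10), 3 * (1:10)))
  expect_error(pca_frame(line), "degenerate")
})

test_that("compute_obb centres on the arithmetic mean and contains the cloud", {
  cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)) +
                        matrix(rep(c(0, 0, 0), each = 8), 8, 3))
  # slight anisotropy so the PCA is well defined
  pts <- cube$points %*% diag(c(1.3, 1.1, 1.0))
  obb <- compute_obb(point_cloud(pts))
  expect_equal(obb$center, colMeans(pts), tolerance = 1e-12)
  for (s in 1:3) {
    cl <- random_cloud(80, seed = s, scale = c(4))
    obb <- compute_obb(cl)
    expect_equal(obb$center, colMeans(cl$points), tolerance = 1e-12)
    proj <- abs(sweep(cl$points, 2, obb$center) %*% t(obb$axes))
    expect_true(all(proj <= matrix(obb$half_extents + 1e-9, nrow(proj), 3,
                                   byrow = TRUE)))
    expect_equal(nrow(obb$corners), 8L)
  }
  # rotation equivariance: axes rotate with the cloud (up to sign/order)
  cl <- with_seed_test(9, point_cloud(cbind(rnorm(300, sd = 3),
                                            rnorm(300, sd = 2),
                                            rnorm(300, sd = 1))))
  R <- rotation_about_axis(c(1, 1, 0), 25)
  obb1 <- compute_obb(cl)
  obb2 <- compute_obb(apply_transform(cl, rigid_transform(R)))
  align <- abs((obb1$axes %*% t(R)) %*% t(obb2$axes))
  expect_equal(sort(diag(align)), c(1, 1, 1), tolerance = 1e-6)
  # coplanar input
  flat <- point_cloud(cbind(matrix(rnorm(40), 20, 2), 0))
  expect_error(compute_obb(flat), "degenerate extent|coplanar")
})

test_that("obb center is translation- and rotation-equivariant", {
  cl <- random_cloud(60, seed = 13, scale = 2)
  tf <- random_rigid(14)
  c1 <- compute_obb(apply_transform(cl, tf))$center
  c2 <- as.numeric(tf$rotation %*% compute_obb(cl)$center) + tf$translation
  expect_equal(c1, c2, tolerance = 1e-9)
})
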