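test_that("pulp horn directions find synthetic horn apexes", {
  # one conical horn along +z
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  ring <- function(r, z) cbind(r * cos(th), r * sin(th), z)
  cone <- point_cloud(rbind(ring(2, 0), ring(1.5, 1), ring(1, 2),
                            ring(0.5, 3), c(0, 0, 3.6)))
  horns <- pulp_horn_feature_directions(cone, c(0, 0, 1), n_horns = 1)
  ang <- acos(sum(horns[[1]]$direction * c(0, 0, 1))) * 180 / pi
  expect_lt(ang, 2)
  # manual overrides pass through verbatim
  manual <- list(pulp_horn_feature(c(1, 2, 3), c(0, 0, 1), "manual"))
  expect_identical(pulp_horn_feature_directions(cone, manual_overrides = manual),
                   manual)
  # four-horn phantom pulp: apexes land near the generator's ground truth
  fx <- fixture_phantom_pair(seed = 2, clean = TRUE)
  horns4 <- pulp_horn_feature_directions(fx$pulp, fx$phantom$occlusal_axis, 4)
  found <- t(vapply(horns4, function(h) h$apex, numeric(3)))
  for (i in seq_len(4)) {
    d <- sqrt(rowSums(sweep(found, 2, fx$phantom$horn_apexes[i, ])^2))
    expect_lt(min(d), 0.3)
  }
  # asking for more horns than exist fails with the count found
  expect_error(pulp_horn_feature_directions(cone, c(0, 0, 1), n_horns = 4,
                                            min_separation = 2),
               "found only")
})

test_that("PHFM retention equals the exhaustive angle oracle and is monotone", {
  cl <- with_seed_test(31, {
    n <- matrix(rnorm(3000), 1000, 3)
    n <- n / sqrt(rowSums(n^2))
    point_cloud(matrix(rnorm(3000), 1000, 3), normals = n)
  })
  horns <- list(pulp_horn_feature(c(0, 0, 0), c(0, 0, 1)),
                pulp_horn_feature(c(0, 0, 0), c(1, 1, 0)))
  dirs <- t(vapply(horns, function(h) h$direction, numeric(3)))
  best <- apply(acos(pmin(pmax(cl$normals %*% t(dirs), -1), 1)) * 180 / pi, 1, min)
  for (g in c(10, 45, 90)) {
    sel <- phfm_select_mapping_points(cl, horns, g)
    expect_identical(sel$indices, which(best <= g))
  }
  # gamma_max = 180 retains everything
  expect_length(phfm_select_mapping_points(cl, horns, 180)$indices, 1000L)
  # retention is monotone in gamma_max
  sizes <- vapply(seq(5, 180, by = 5), function(g)
    length(phfm_select_mapping_points(cl, horns, g)$indices), 0L)
  expect_true(all(diff(sizes) >= 0))
  # a normal exactly along a horn direction is retained at any threshold
  one <- point_cloud(matrix(0, 2, 3) + rbind(c(0, 0, 0), c(1, 0, 0)),
                     normals = rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_true(1 %in% phfm_select_mapping_points(one, horns[1], 20)$indices)
  expect_error(phfm_select_mapping_points(one, horns[2], 0.001), "gamma_max")
})

test_that("MLS patches recover planes and quadrics", {
  # points on a tilted plane: quadratic coefficients vanish
  g <- as.matrix(expand.grid(x = seq(-1, 1, 0.2), y = seq(-1, 1, 0.2)))
  plane_pts <- cbind(g, 0.3 * g[, 1] - 0.2 * g[, 2])
  pl <- fit_mls_patch(point_cloud(plane_pts), center_index = 61,
                      fit_radius = 1, min_neighbors = 24)
  expect_true(pl$ok)
  expect_lt(max(abs(pl$coeffs[4:6])), 1e-8)
  # points sampled from z' = x'^2 + y'^2 around the origin
  gq <- as.matrix(expand.grid(x = seq(-0.3, 0.3, 0.06), y = seq(-0.3, 0.3, 0.06)))
  quad_pts <- cbind(gq, gq[, 1]^2 + gq[, 2]^2)
  ctr <- which(gq[, 1] == 0 & gq[, 2] == 0)
  pq <- fit_mls_patch(point_cloud(quad_pts), center_index = ctr,
                      fit_radius = 0.6, min_neighbors = 60)
  expect_true(pq$ok)
  # in the fitted local frame the paraboloid keeps a3 ~ a5, a4 ~ 0
  expect_equal(pq$coeffs[4], pq$coeffs[6], tolerance = 1e-3)
  expect_lt(abs(pq$coeffs[5]), 1e-3)
  expect_equal(pq$coeffs[4], 1, tolerance = 0.05)
  expect_gt(sum(pq$axes[3, ] * c(0, 0, 1)), 0)  # z axis oriented canonically
  # an under-determined neighbourhood flags the fallback
  few <- point_cloud(matrix(rnorm(15), 5, 3))
  pf <- fit_mls_patch(few, 1, fit_radius = 10, min_neighbors = 24)
  expect_false(pf$ok)
})

test_that("patch sampling covers the disk lattice and stays on the quadric", {
  g <- as.matrix(expand.grid(x = seq(-1, 1, 0.1), y = seq(-1, 1, 0.1)))
  pts <- cbind(g, 0.5 * g[, 1]^2 - 0.3 * g[, 1] * g[, 2])
  ctr <- which(g[, 1] == 0 & g[, 2] == 0)
  p <- fit_mls_patch(point_cloud(pts), ctr, fit_radius = 0.8, min_neighbors = 100)
  p <- sample_patch(p, sample_radius = 0.3, span = 0.1)
  # lattice count oracle: grid nodes of spacing 0.1 inside the 0.3 disk
  m <- floor(0.3 / 0.1 + 1e-9)
  nodes <- expand.grid(gx = -m:m, gy = -m:m)
  expected <- sum(nodes$gx^2 + nodes$gy^2 <= (0.3 / 0.1)^2 + 1e-9)
  expect_equal(nrow(p$samples), expected)
  # every sample satisfies the quadric equation in the local frame
  loc <- sweep(p$samples, 2, p$origin) %*% t(p$axes)
  zq <- p$coeffs[1] + p$coeffs[2] * loc[, 1] + p$coeffs[3] * loc[, 2] +
    p$coeffs[4] * loc[, 1]^2 + p$coeffs[5] * loc[, 1] * loc[, 2] +
    p$coeffs[6] * loc[, 2]^2
  expect_lt(max(abs(loc[, 3] - zq)), 1e-6)
  # span wider than the disk leaves the single centre sample, with warning
  expect_warning(p1 <- sample_patch(p, sample_radius = 0.05, span = 0.2),
                 "centre sample")
  expect_equal(nrow(p1$samples), 1L)
})

test_that("point-to-surface matching projects onto local geometry", {
  # a dense plane: an offset query point maps to (near) its foot point
  g <- as.matrix(expand.grid(x = seq(-2, 2, 0.1), y = seq(-2, 2, 0.1)))
  plane <- point_cloud(cbind(g, 0))
  sel <- list(indices = seq_len(nrow(g)), gamma_max = 180)
  class(sel) <- "mapping_selection"
  q <- c(0.03, 0.04, 0.5)   # off-lattice, 0.5 mm above the plane
  m <- match_point_to_surface(q, plane, sel, k_y = 8, k_c = 24,
                              fit_radius = 0.3, sample_radius = 0.3,
                              span = 0.05)
  expect_equal(m$mode, "point_surface")
  expect_lt(abs(m$target[3]), 1e-6)                       # on the plane
  expect_lt(sqrt(sum((m$target[1:2] - q[1:2])^2)), 0.05 / sqrt(2) + 1e-9)
  # a query on the cloud matches itself up to the sampling span
  m2 <- match_point_to_surface(c(0.1, 0.1, 0), plane, sel, span = 0.05,
                               fit_radius = 0.3, sample_radius = 0.3)
  expect_lt(sqrt(sum((m2$target - c(0.1, 0.1, 0))^2)), 0.05)
  # vanishing radii: matching degenerates to the nearest neighbour
  cl <- random_cloud(500, seed = 41)
  qs <- with_seed_test(42, matrix(rnorm(600), 200, 3) * 0.9)
  elig <- rep(TRUE, 500)
  res <- phmsr:::cpp_match_correspondences(cl$points, qs, elig, 24L,
                                           1e-9, 1e-9, 1e-9 / 3)
  nn <- phmsr:::cpp_nn1(cl$points, qs)
  same <- rowSums((res$matched - cl$points[nn$index, ])^2) < 1e-18
  expect_gte(mean(same), 0.99)
})

test_that("surface matching never lands farther than NN plus the span", {
  fx <- fixture_phantom_pair(seed = 3, density = 6, clean = TRUE)
  crown <- estimate_normals(fx$crown, 10)
  qs <- fx$scan$points[seq(1, n_points(fx$scan), by = 5), , drop = FALSE]
  elig <- rep(TRUE, n_points(crown))
  span <- 0.1 / 3
  res <- phmsr:::cpp_match_correspondences(crown$points, qs, elig, 24L,
                                           0.1, 0.1, span)
  nn <- phmsr:::cpp_nn1(crown$points, qs)
  d_surf <- sqrt(rowSums((res$matched - qs)^2))
  expect_true(all(d_surf <= nn$dist + span + 1e-9))
})
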