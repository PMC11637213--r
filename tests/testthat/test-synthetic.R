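test_that("phantoms are pure functions of their seed", {
  p1 <- make_tooth_phantom(seed = 42)
  p2 <- make_tooth_phantom(seed = 42)
  expect_identical(p1$crown_vertices, p2$crown_vertices)
  expect_identical(p1$pulp_vertices, p2$pulp_vertices)
  expect_identical(p1$horn_apexes, p2$horn_apexes)
  s1 <- make_scan_cloud(p1, density_per_mm2 = 5, seed = 7)
  s2 <- make_scan_cloud(p2, density_per_mm2 = 5, seed = 7)
  expect_identical(s1$points, s2$points)
  c1 <- make_cbct_cloud(p1, seed = 7)
  c2 <- make_cbct_cloud(p2, seed = 7)
  expect_identical(c1$crown$points, c2$crown$points)
})

test_that("phantom anatomy satisfies its own invariants", {
  ph <- make_tooth_phantom(n_cusps = 4, seed = 1)
  # four horns, pairwise apart
  expect_equal(nrow(ph$horn_apexes), 4L)
  expect_gt(min(dist(ph$horn_apexes)), 1)
  # each horn apex lies beneath its cusp apex (same direction, lower)
  for (i in 1:4) {
    d <- sqrt(rowSums(sweep(ph$cusp_apexes[, 1:2], 2, ph$horn_apexes[i, 1:2])^2))
    j <- which.min(d)
    expect_lt(ph$horn_apexes[i, 3], ph$cusp_apexes[j, 3])
  }
  # pulp strictly inside the crown: positive crown distance margin
  expect_lt(max(surface_distance(ph, ph$pulp_vertices, "crown")), 0)
  # single-cusp phantom: one horn close to the cusp axis
  ph1 <- make_tooth_phantom(n_cusps = 1, seed = 2)
  expect_equal(nrow(ph1$horn_apexes), 1L)
  axis_xy <- ph1$cusp_apexes[1, 1:2] / sqrt(sum(ph1$cusp_apexes[1, 1:2]^2))
  horn_xy <- ph1$horn_apexes[1, 1:2]
  off_axis <- sqrt(sum((horn_xy - sum(horn_xy * axis_xy) * axis_xy)^2))
  expect_lt(off_axis, 0.5)
  # infeasible geometry is rejected
  expect_error(make_tooth_phantom(pulp_scale = 0.95, seed = 1), "infeasible")
})

test_that("scan clouds carry half-normal surface noise", {
  ph <- make_tooth_phantom(seed = 3)
  exact <- make_scan_cloud(ph, density_per_mm2 = 10, noise_sigma_mm = 0, seed = 3)
  # noiseless points lie on the crown surface (mesh chord error only)
  expect_lt(max(abs(surface_distance(ph, exact))), 0.02)
  # with noise, the mean |distance| approaches sigma * sqrt(2/pi)
  sigma <- 0.05
  noisy <- make_scan_cloud(ph, density_per_mm2 = 80, noise_sigma_mm = sigma,
                           seed = 4)
  expect_gt(n_points(noisy), 1e4)
  expect_equal(mean(abs(surface_distance(ph, noisy))), sigma * sqrt(2 / pi),
               tolerance = 0.1)
})

test_that("CBCT clouds respect the quantisation bound and outlier count", {
  ph <- make_tooth_phantom(seed = 5)
  # all degradation off, raw isosurface: every vertex lies on a
  # tetrahedron edge of its cell, so the quantisation bound is half the
  # body diagonal, sqrt(3)/2 voxels
  raw <- make_cbct_cloud(ph, noise_sigma_mm = 0, outlier_frac = 0,
                         dropout_frac = 0, seed = 5, smooth_iters = 0)
  expect_lt(max(abs(surface_distance(ph, raw$crown))), sqrt(3) / 2 * 0.25 + 0.02)
  # exactly floor(0.2 n) points are displaced beyond 1 mm
  out <- make_cbct_cloud(ph, noise_sigma_mm = 0, outlier_frac = 0.2,
                         dropout_frac = 0, seed = 6)
  d <- abs(surface_distance(ph, out$crown))
  n_far <- sum(d > 0.9)
  expect_equal(n_far, length(out$outlier_indices))
  expect_true(all(d[out$outlier_indices] > 0.9))
  # crown and pulp clouds are rigidly consistent: a transform fitted on
  # the crown maps the pulp with no extra error
  tf <- random_rigid(61, angle = 15, trans = 3)
  crown_moved <- apply_transform(out$crown, tf)
  est <- phmsr:::kabsch(out$crown$points, crown_moved$points)
  pulp_pred <- apply_transform(out$pulp, est)
  pulp_true <- apply_transform(out$pulp, tf)
  expect_lt(max(abs(pulp_pred$points - pulp_true$points)), 1e-9)
})

test_that("pose perturbations are bounded, invertible and seeded", {
  cl <- random_cloud(100, seed = 71, scale = 4)
  # zero ranges give the identity
  p0 <- perturb_pose(cl, NULL, angle_deg = 0, trans_mm = 0, seed = 1)
  expect_equal(p0$transform$rotation, diag(3))
  expect_equal(p0$cloud$points, cl$points)
  # the returned transform reproduces the moved cloud and inverts cleanly
  p1 <- perturb_pose(cl, "small", seed = 2)
  expect_equal(apply_transform(cl, p1$transform)$points, p1$cloud$points)
  back <- apply_transform(p1$cloud, invert_transform(p1$transform))
  expect_equal(back$points, cl$points, tolerance = 1e-12)
  # preset magnitudes hold across seeds
  angs <- vapply(1:100, function(s)
    rotation_angle_deg(perturb_pose(cl, "small", seed = s)$transform$rotation), 0)
  expect_true(all(angs <= 5))
  large <- perturbation_preset("large")
  expect_gt(large$rotation_range_deg, perturbation_preset("small")$rotation_range_deg)
  expect_gt(large$translation_range_mm, perturbation_preset("small")$translation_range_mm)
})

test_that("segmentation phantom volumes match their analytic solids", {
  pv <- make_segmentation_phantom_volume(noise_sigma = 0)
  # exact intensity levels when noiseless
  expect_setequal(unique(as.numeric(pv$volume$voxels)), c(50, 100, 150))
  # truth labels partition the volume
  expect_true(all(pv$truth$labels %in% c(0L, 2L, 3L)))
  # voxel counts against the analytic capped-cylinder volumes
  sp <- 0.25
  vol_capped <- function(R, zb, zt) pi * R^2 * (zt - zb) + 2 / 3 * pi * R^3
  ctr_z <- (40 / 2) * sp
  zb <- ctr_z - (5 + 3.5) / 2; zt <- zb + 5
  v_pulp <- vol_capped(1.6, zb + 2 * sp, zt)
  v_tooth <- vol_capped(3.5, zb, zt) - v_pulp
  expect_equal(sum(pv$truth$labels == 2L) * sp^3, v_tooth, tolerance = 0.02)
  # the pulp solid is only 6.4 voxels in radius, so its lattice count
  # fluctuates a little more around the continuum volume
  expect_equal(sum(pv$truth$labels == 3L) * sp^3, v_pulp, tolerance = 0.04)
})
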