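test_that("cloud RMSE matches the brute-force double loop", {
  a <- random_cloud(120, seed = 121, scale = 2)
  b <- random_cloud(200, seed = 122, scale = 2)
  # exhaustive oracle
  dd <- outer(seq_len(120), seq_len(200), function(i, j)
    sqrt(rowSums((a$points[i, , drop = FALSE] - b$points[j, , drop = FALSE])^2)))
  oracle <- sqrt(mean(apply(dd, 1, min)^2))
  expect_equal(cloud_rmse(a, b), oracle, tolerance = 1e-12)
  # identical clouds score exactly zero
  expect_identical(cloud_rmse(a, a), 0)
  # dense plane against itself offset along the normal
  g <- as.matrix(expand.grid(x = seq(0, 5, 0.1), y = seq(0, 5, 0.1)))
  plane <- point_cloud(cbind(g, 0))
  lifted <- point_cloud(cbind(g, 0.2))
  expect_equal(cloud_rmse(plane, lifted), 0.2, tolerance = 0.002)
  expect_error(cloud_rmse(a, point_cloud(matrix(numeric(0), 0, 3))), "non-empty")
})

test_that("crown-pulp deviations reproduce analytic pose offsets", {
  fx <- fixture_phantom_pair(seed = 12, density = 5, clean = TRUE)
  crown <- downsample_cloud(fx$scan, 800)
  pulp <- downsample_cloud(fx$pulp, 800)
  # identical poses: exactly zero
  dev0 <- crown_pulp_deviation(pulp, crown, crown)
  expect_equal(dev0$cppd, 0)
  expect_equal(dev0$cpod, 0)
  # pure 3-4-5 translation: CPPD = 0.5 mm, CPOD = 0
  moved <- apply_transform(crown, rigid_transform(translation = c(0.3, 0.4, 0)))
  dev1 <- crown_pulp_deviation(pulp, crown, moved)
  expect_equal(dev1$cppd, 0.5, tolerance = 1e-9)
  expect_lt(dev1$cpod, 1e-9)
  # pure 2-degree rotation about the pulp-frame z axis through the crown
  # centroid: CPOD = 2 degrees, CPPD = 0
  fp <- pca_frame(pulp)
  axis_z <- fp$axes[3, ]
  ctr <- colMeans(crown$points)
  R <- rotation_about_axis(axis_z, 2)
  rot2 <- apply_transform(crown,
                          rigid_transform(R, ctr - as.numeric(R %*% ctr)))
  dev2 <- crown_pulp_deviation(pulp, crown, rot2)
  expect_equal(dev2$cpod, 2, tolerance = 1e-6)
  expect_lt(dev2$cppd, 1e-6)
})

test_that("crown-pulp deviation is invariant to a common rigid motion", {
  fx <- fixture_phantom_pair(seed = 13, density = 5, clean = TRUE)
  crown <- downsample_cloud(fx$scan, 600)
  pulp <- downsample_cloud(fx$pulp, 600)
  moved <- apply_transform(crown, random_rigid(131, angle = 3, trans = 0.5))
  dev <- crown_pulp_deviation(pulp, crown, moved)
  g <- random_rigid(132, angle = 20, trans = 4)
  dev_g <- crown_pulp_deviation(apply_transform(pulp, g),
                                apply_transform(crown, g),
                                apply_transform(moved, g))
  expect_equal(dev_g$cppd, dev$cppd, tolerance = 1e-6)
  expect_equal(dev_g$cpod, dev$cpod, tolerance = 1e-6)
  # symmetric under swapping which pose is called truth
  dev_swap <- crown_pulp_deviation(pulp, moved, crown)
  expect_equal(dev_swap$cppd, dev$cppd, tolerance = 1e-9)
  expect_equal(dev_swap$cpod, dev$cpod, tolerance = 1e-9)
})

test_that("evaluate_run emits complete rows and honest NAs", {
  fx <- fixture_phantom_pair(seed = 14, density = 5, clean = TRUE)
  clouds <- list(scan = fx$scan,
                 cbct_crown = downsample_cloud(fx$crown, 800),
                 pulp = downsample_cloud(fx$pulp, 800))
  perfect <- registration_result(rigid_transform(), "icp", 1, TRUE)
  row <- evaluate_run(perfect, clouds, truth = rigid_transform(),
                      seed = 1, preset = "small")
  expect_equal(row$cppd, 0)
  expect_equal(row$cpod, 0)
  expect_equal(row$rot_error_deg, 0)
  # missing truth: crown-pulp metrics NA, RMSE still present
  row2 <- evaluate_run(perfect, clouds)
  expect_true(is.na(row2$cppd) && is.na(row2$cpod))
  expect_true(is.finite(row2$rmse))
})

test_that("batch summaries match direct recomputation", {
  fx <- fixture_phantom_pair(seed = 15, density = 4, clean = TRUE)
  crown <- downsample_cloud(fx$crown, 500)
  pulp <- downsample_cloud(fx$pulp, 500)
  rows <- do.call(rbind, lapply(1:5, function(s) {
    pert <- perturb_pose(fx$scan, "small", seed = 150 + s)
    res <- icp_register(pert$cloud, crown, tol_mm = 1e-3)
    evaluate_run(res, list(scan = pert$cloud, cbct_crown = crown, pulp = pulp),
                 invert_transform(pert$transform), seed = s, preset = "small")
  }))
  summ <- summarize_runs(rows)
  expect_equal(nrow(summ), 1L)
  expect_equal(summ$n, 5L)
  expect_equal(summ$cpod_mean, mean(rows$cpod), tolerance = 1e-12)
  expect_equal(summ$cpod_sd, sd(rows$cpod), tolerance = 1e-12)
  expect_equal(summ$rmse_mean, sum(rows$rmse) / 5, tolerance = 1e-12)
})
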