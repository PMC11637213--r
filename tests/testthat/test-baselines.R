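test_that("classic ICP recovers exact motions of identical clouds", {
  cl <- random_cloud(200, seed = 71, scale = 3)
  res <- icp_register(cl, cl)
  expect_lt(rotation_angle_deg(res$transform$rotation), 1e-9)
  expect_lt(sqrt(sum(res$transform$translation^2)), 1e-9)
  # pure translation of a dense phantom crown
  fx <- fixture_phantom_pair(seed = 8, density = 8, clean = TRUE)
  moved <- apply_transform(fx$scan, rigid_transform(translation = c(0.5, 0, 0)))
  res2 <- icp_register(moved, fx$scan, tol_mm = 1e-6, max_iter = 200)
  back <- res2$transform$translation
  expect_lt(sqrt(sum((back + c(0.5, 0, 0))^2)), 0.01)
  expect_error(icp_register(point_cloud(cbind(1:5, 1:5, 1:5) * 1.0), cl),
               "degenerate|collinear")
})

test_that("sparse ICP beats classic ICP under gross outliers", {
  # gross outliers in the free cloud: every one of them contributes a
  # large residual to the pose solve, which the lp shrinkage suppresses
  # and least squares does not. The start is near-aligned — robustness to
  # outliers, not capture range, is the lp solver's claim
  fx <- fixture_phantom_pair(seed = 9, density = 6, clean = TRUE)
  target <- downsample_cloud(fx$crown, 3000)
  pert <- perturb_pose(fx$scan, NULL, angle_deg = 1, trans_mm = 0.2, seed = 96)
  src <- with_seed_test(196, {
    pts <- pert$cloud$points
    idx <- sample.int(nrow(pts), floor(0.2 * nrow(pts)))
    dir <- matrix(rnorm(3 * length(idx)), length(idx), 3)
    pts[idx, ] <- pts[idx, ] + runif(length(idx), 5, 10) *
      dir / sqrt(rowSums(dir^2))
    point_cloud(pts)
  })
  truth <- invert_transform(pert$transform)
  ctr <- colMeans(src$points)
  e_icp <- transform_error(icp_register(src, target,
                                        tol_mm = 1e-6)$transform, truth, ctr)
  e_sicp <- transform_error(sparse_icp_register(src, target)$transform,
                            truth, ctr)
  expect_lt(e_sicp$rot_deg, e_icp$rot_deg)
})

test_that("rigid CPD recovers rotations and its NLL never increases", {
  fx <- fixture_phantom_pair(seed = 10, density = 4, clean = TRUE)
  src <- downsample_cloud(fx$scan, 300)
  res0 <- cpd_rigid_register(src, src)
  expect_lt(rotation_angle_deg(res0$transform$rotation), 1e-4)
  # a 10-degree rotation of the same 300-point cloud
  pert <- perturb_pose(src, NULL, angle_deg = 10, trans_mm = 0, seed = 101)
  res <- cpd_rigid_register(pert$cloud, src, outlier_weight = 0.1,
                            max_iter = 150)
  e <- transform_error(res$transform, invert_transform(pert$transform),
                       colMeans(pert$cloud$points))
  expect_lt(e$rot_deg, 0.5)
  expect_true(all(diff(res$diagnostics$nll) <= 1e-6))
})

test_that("all methods are invariant to a common rigid motion", {
  fx <- fixture_phantom_pair(seed = 11, density = 4, clean = TRUE)
  src <- downsample_cloud(fx$scan, 250)
  tgt <- downsample_cloud(fx$crown, 600)
  pert <- perturb_pose(src, NULL, angle_deg = 4, trans_mm = 0.5, seed = 111)
  g <- random_rigid(112, angle = 30, trans = 5)
  runs <- list(
    icp = function(s, t) icp_register(s, t, tol_mm = 1e-4)$transform,
    sicp = function(s, t) sparse_icp_register(s, t, max_outer_iter = 25)$transform,
    cpd = function(s, t) cpd_rigid_register(s, t, max_iter = 30)$transform
  )
  for (nm in names(runs)) {
    t_plain <- runs[[nm]](pert$cloud, tgt)
    t_conj <- runs[[nm]](apply_transform(pert$cloud, g), apply_transform(tgt, g))
    # conjugation identity: T' = g T g^-1
    expected <- compose_transform(g, compose_transform(t_plain, invert_transform(g)))
    expect_lt(max(abs(t_conj$rotation - expected$rotation)), 1e-6)
    expect_lt(max(abs(t_conj$translation - expected$translation)), 1e-5)
  }
})
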