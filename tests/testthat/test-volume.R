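test_that("the hybrid filter leaves structure-free slices alone and denoises edges", {
  const_vol <- volume_image(array(77, c(16, 16, 3)), 0.25)
  out <- hybrid_filter(const_vol)
  expect_lt(max(abs(out$voxels - 77)), 1e-6)
  # argument contracts
  expect_error(hybrid_filter(const_vol, window = 4), "odd")
  expect_error(hybrid_filter(volume_image(array(1.0 * (1:27), c(3, 3, 3))), window = 5),
               "thinner")
  # a noisy step edge gets closer to the clean image
  clean <- array(50, c(32, 32, 4))
  clean[17:32, , ] <- 150
  noisy <- with_seed_test(81, clean + array(rnorm(length(clean), 0, 10), dim(clean)))
  filt <- hybrid_filter(volume_image(noisy, 0.25))
  mse_before <- mean((noisy - clean)^2)
  mse_after <- mean((filt$voxels - clean)^2)
  expect_lt(mse_after, mse_before)
  # output never expands the input intensity range
  expect_gte(min(filt$voxels), min(noisy) - 1e-6)
  expect_lte(max(filt$voxels), max(noisy) + 1e-6)
})

test_that("adaptive SCM parameters follow the printed update rules", {
  sl <- matrix(c(50, 150, 100, 100), 2, 2)  # mean 100, max 150
  p <- scm_adaptive_params(sl, C = 50, a = 0.2)
  expect_equal(p$alpha_e, 0.5)              # C / mu
  expect_equal(p$V_E, 200)                  # 2 mu
  expect_equal(p$beta, 0.2 * log(100))      # a ln(mu)
  expect_equal(p$alpha_u, log(1 / var(as.numeric(sl))))
  expect_equal(p$E0, 150)                   # max
  # independent recomputation on a random slice
  sl2 <- with_seed_test(82, matrix(runif(400, 10, 200), 20, 20))
  p2 <- scm_adaptive_params(sl2, C = 5, a = 0.1)
  m <- sum(sl2) / length(sl2)
  v <- sum((sl2 - m)^2) / (length(sl2) - 1)
  expect_equal(p2$alpha_e, 5 / m)
  expect_equal(p2$V_E, 2 * m)
  expect_equal(p2$alpha_u, log(1 / v))
  expect_equal(p2$E0, max(sl2))
  # scale awareness: doubling intensities doubles V_E and E0, halves alpha_e
  p3 <- scm_adaptive_params(2 * sl2, C = 5, a = 0.1)
  expect_equal(p3$V_E, 2 * p2$V_E)
  expect_equal(p3$E0, 2 * p2$E0)
  expect_equal(p3$alpha_e, p2$alpha_e / 2)
  # degenerate inputs
  expect_error(scm_adaptive_params(matrix(5, 3, 3), C = 1, a = 1), "variance")
  expect_error(scm_adaptive_params(matrix(-1, 2, 2) + c(0, 0, 0, 1), C = 1, a = 1),
               "positive")
})

test_that("SCM slice segmentation separates intensity classes", {
  # uniform image: everything fires in the same pulse
  uni <- matrix(0.5, 20, 20) + diag(20) * 1e-9  # epsilon variance
  p <- scm_adaptive_params(uni, C = 0.01, a = -0.02)
  seg <- scm_segment_slice(uni, p)
  expect_equal(length(unique(seg$firing[!is.na(seg$firing)])), 1L)
  # disk phantom, noiseless: per-region Dice 1
  g <- as.matrix(expand.grid(1:48, 1:48))
  disk <- matrix(50, 48, 48)
  disk[g[rowSums(sweep(g, 2, c(24, 24))^2) <= 144, ]] <- 200
  dn <- disk / 255
  seg0 <- suppressWarnings(
    scm_segment_slice(dn, scm_adaptive_params(dn, C = 0.01, a = -0.02)))
  lab_disk <- seg0$labels == seg0$labels[24, 24]
  expect_gte(dice_coefficient(lab_disk, disk == 200), 0.99)
  # with Gaussian noise and adaptive parameters the Dice stays high
  noisy <- with_seed_test(83, (disk + matrix(rnorm(48 * 48, 0, 5), 48, 48)) / 255)
  seg1 <- suppressWarnings(
    scm_segment_slice(noisy, scm_adaptive_params(noisy, C = 0.01, a = -0.02)))
  lab1 <- seg1$labels == seg1$labels[24, 24]
  expect_gte(dice_coefficient(lab1, disk == 200), 0.95)
  # deterministic: same input, same labels
  seg2 <- suppressWarnings(
    scm_segment_slice(noisy, scm_adaptive_params(noisy, C = 0.01, a = -0.02)))
  expect_identical(seg1$labels, seg2$labels)
  expect_identical(seg1$firing, seg2$firing)
})

test_that("tooth and pulp segmentation recovers the phantom masks", {
  pv <- make_segmentation_phantom_volume(noise_sigma = 5, seed = 2)
  lab <- suppressWarnings(segment_tooth_and_pulp(hybrid_filter(pv$volume)))
  expect_gte(dice_coefficient(lab$labels == lab$legend[["tooth"]],
                              pv$truth$labels == 2L), 0.9)
  expect_gte(dice_coefficient(lab$labels == lab$legend[["pulp"]],
                              pv$truth$labels == 3L), 0.9)
  # structure-free volume: empty labels plus a warning
  flat <- volume_image(array(10, c(12, 12, 6)), 0.25)
  expect_warning(lab0 <- segment_tooth_and_pulp(flat), "no.*structure|empty")
  expect_true(all(lab0$labels == 0L))
  # two disjoint teeth produce two tooth components
  v2 <- array(50, c(48, 24, 20))
  g <- as.matrix(expand.grid(x = 1:48, y = 1:24, z = 1:20))
  inside <- function(cx) (g[, 1] - cx)^2 + (g[, 2] - 12)^2 <= 36 &
    g[, 3] >= 4 & g[, 3] <= 16
  v2[g[inside(12), ]] <- 150
  v2[g[inside(36), ]] <- 150
  lab2 <- suppressWarnings(segment_tooth_and_pulp(volume_image(v2, 0.25)))
  expect_equal(attr(lab2, "n_tooth_components"), 2L)
})

test_that("isosurface extraction honours radius, smoothing and roughness", {
  m <- array(0, c(40, 40, 40))
  g <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  m[g[rowSums(sweep(g, 2, c(20, 20, 20))^2) <= 100, ]] <- 1
  lv <- label_volume(array(as.integer(m), c(40, 40, 40)),
                     c(background = 0L, tooth = 1L), 0.25)
  # a 10-voxel ball at 0.25 mm spacing has radius 2.5 mm
  cl <- extract_surface_cloud(lv, "tooth", smoothing_iters = 5)
  ctr <- colMeans(cl$points)
  r <- sqrt(rowSums(sweep(cl$points, 2, ctr)^2))
  expect_equal(mean(r), 2.5, tolerance = 0.25 / 2.5)
  # smoothing_iters = 0 returns the raw isosurface vertices
  cl0 <- extract_surface_cloud(lv, "tooth", smoothing_iters = 0)
  expect_equal(cl0$points, attr(cl0, "vertices_raw"))
  # normals are unit and oriented outward
  expect_equal(sqrt(rowSums(cl$normals^2)), rep(1, n_points(cl)), tolerance = 1e-9)
  expect_gte(mean(rowSums(cl$normals * sweep(cl$points, 2, ctr)) > 0), 0.99)
  # smoothing reduces mean local roughness monotonically
  faces <- attr(cl0, "faces")
  roughness <- function(V) {
    acc <- matrix(0, nrow(V), 3); cnt <- numeric(nrow(V))
    for (j in 1:3) {
      o <- faces[, j]; nb1 <- faces[, (j %% 3) + 1]
      acc[o, ] <- acc[o, ] + V[nb1, ]; cnt[o] <- cnt[o] + 1
    }
    mean(sqrt(rowSums((acc / cnt - V)^2)), na.rm = TRUE)
  }
  vr <- attr(cl0, "vertices_raw") / 0.25
  rough <- vapply(0:10, function(k) {
    V <- if (k == 0) vr else phmsr:::cpp_laplacian_smooth(vr, faces, k, 0.5)
    roughness(V)
  }, 0)
  expect_true(all(diff(rough) < 0))
  # contract errors
  expect_error(extract_surface_cloud(lv, 7L), "absent")
  expect_error(extract_surface_cloud(lv, "pulp"), "not in legend")
})
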