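# Shared fixtures, generated in code. The small phantom pair keeps the
# per-file tests fast; heavier protocol runs live in test-acceptance.R.

fixture_phantom_pair <- function(seed = 1, density = 10, clean = FALSE) {
  ph <- make_tooth_phantom(seed = seed)
  scan <- make_scan_cloud(ph, density_per_mm2 = density, seed = seed)
  cb <- if (clean)
    make_cbct_cloud(ph, noise_sigma_mm = 0, outlier_frac = 0,
                    dropout_frac = 0, seed = seed)
  else make_cbct_cloud(ph, seed = seed)
  keep <- cb$crown$points[, 3] > ph$margin_z
  crown <- point_cloud(cb$crown$points[keep, , drop = FALSE],
                       source_tag = "cbct_crown")
  list(phantom = ph, scan = scan, crown = crown,
       crown_full = cb$crown, pulp = cb$pulp)
}

random_cloud <- function(n, seed = 1, scale = 1) {
  with_seed_test(seed, point_cloud(matrix(rnorm(3 * n), n, 3) * scale))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

random_rigid <- function(seed = 1, angle = 30, trans = 2) {
  with_seed_test(seed, {
    ax <- rnorm(3)
    rigid_transform(rotation_about_axis(ax, runif(1, 0, angle)),
                    runif(3, -trans, trans))
  })
}
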