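# Run configuration: every tunable of the pipeline in one flat list, with
# defaults resolving exactly to the published settings.

#' Build a run configuration
#'
#' Resolves all pipeline parameters. The deviation presets fix the
#' mapping-surface settings: small initial deviation uses
#' `gamma_max = 20` degrees and fit/sample radius `r = 0.1` mm; large uses
#' 25 degrees and 0.3 mm. The sparse solver defaults are `p = 0.5`,
#' `mu = 10`, `n2 = 2`, `ns = 3`; classic ICP runs at most 100 iterations
#' with a 0.1 mm allowable error; CPD uses outlier weight 0.1. The
#' neighbourhood sizes default to `k_y = 8`, `k_c = 24` (respecting
#' `k_c >= 3 k_y`); the patch sampling span defaults to `fit_radius / 3`.
#' Mapping points and their neighbours enter the pose solve with
#' increased weight (`surface_weight`, default 5), and correspondences
#' farther than `trim_factor` (default 3) times the median matched
#' distance are dropped from the solve.
#'
#' @param method one of `"phmsr"`, `"sicp"`, `"icp"`, `"cpd"`.
#' @param deviation_preset `"small"` or `"large"`.
#' @param ... overrides for any configuration field.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(method = c("phmsr", "sicp", "icp", "cpd"),
                       deviation_preset = c("small", "large"), ...) {
  method <- match.arg(method)
  deviation_preset <- match.arg(deviation_preset)
  small <- deviation_preset == "small"
  cfg <- list(
    method = method,
    deviation_preset = deviation_preset,
    gamma_max = if (small) 20 else 25,
    fit_radius = if (small) 0.1 else 0.3,
    sample_radius = if (small) 0.1 else 0.3,
    span = NULL,                  # resolved to fit_radius / 3 at run time
    k_y = 8,
    k_c = 24,
    surface_weight = 5,
    trim_factor = 3,
    p = 0.5,
    mu = 10,
    n2 = 2,
    ns = 3,
    icp_max_iter = 100,
    icp_tol_mm = 0.1,
    cpd_outlier_weight = 0.1,
    cpd_max_iter = 60,
    cpd_tol = 1e-6,
    scm_C = 0.01,
    scm_a = -0.02,
    scm_n_iter = 40,
    nlm_block = 2,
    nlm_window = 5,
    nlm_decay = 10,
    wavelet_levels = 2,
    n_horns = 4,
    normal_k = 10,
    max_outer_iter = 50,
    rot_tol_deg = 0.01,
    trans_tol_mm = 1e-3,
    seed = 1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(ov)] <- ov
  if (cfg$k_c < 3 * cfg$k_y)
    stop("k_c must be at least 3 * k_y")
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s, %s deviation: gamma_max %g deg, r %g mm, p %g, mu %g\n",
              x$method, x$deviation_preset, x$gamma_max, x$fit_radius, x$p, x$mu))
  invisible(x)
}

#' Register with any configured method
#'
#' Dispatches to the mapping-surface method or a baseline from one
#' [run_config()], so benchmark harnesses stay method-agnostic.
#'
#' @param scan free [point_cloud()].
#' @param cbct_crown fixed [point_cloud()].
#' @param pulp pulp cloud (required by `"phmsr"`, ignored by baselines).
#' @param config a [run_config()].
#' @return a [registration_result()].
#' @export
register_with_config <- function(scan, cbct_crown, pulp = NULL,
                                 config = run_config()) {
  switch(config$method,
         phmsr = register_phmsr(scan, cbct_crown, pulp, config = config,
                                deviation_preset = config$deviation_preset),
         sicp = sparse_icp_register(scan, cbct_crown, p = config$p,
                                    mu = config$mu, n2 = config$n2,
                                    ns = config$ns,
                                    max_outer_iter = config$max_outer_iter),
         icp = icp_register(scan, cbct_crown, max_iter = config$icp_max_iter,
                            tol_mm = config$icp_tol_mm),
         cpd = cpd_rigid_register(scan, cbct_crown,
                                  outlier_weight = config$cpd_outlier_weight,
                                  max_iter = config$cpd_max_iter,
                                  tol = config$cpd_tol))
}
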