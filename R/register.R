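# The PHMSR registration loop: pulp-horn feature mapping, point-to-surface
# correspondence search against MLS mapping surfaces, and the sparse lp
# ADMM pose solver, iterated to convergence.

#' Construct a registration result
#' @param transform final [rigid_transform()] mapping the free cloud into
#'   the fixed cloud's frame.
#' @param method method name.
#' @param iterations outer iterations run.
#' @param converged logical convergence flag.
#' @param diagnostics per-iteration data frame.
#' @param params parameter list used.
#' @return object of class `registration_result`.
#' @export
registration_result <- function(transform, method, iterations, converged,
                                diagnostics = NULL, params = list()) {
  structure(list(transform = transform, method = method,
                 iterations = iterations, converged = converged,
                 diagnostics = diagnostics, params = params),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s: %d iterations, %s\n", x$method,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  print(x$transform)
  invisible(x)
}

#' Estimate the occlusal axis of a crown/pulp pair
#'
#' For a cropped (open) crown shell the mean outward surface normal points
#' occlusally: the side-wall normals cancel azimuthally while the occlusal
#' table's normals add up. When the crown is a closed surface (mean normal
#' near zero) the crown's third (least-variance) PCA axis is used instead,
#' with its sign fixed by the skewness of the pulp projections — the pulp
#' horns protrude occlusally and skew the distribution toward the biting
#' surface.
#'
#' @param crown,pulp [point_cloud()]s in a common frame; the crown needs
#'   normals (estimated on the fly if absent).
#' @return unit occlusal axis.
#' @export
estimate_occlusal_axis <- function(crown, pulp) {
  if (is.null(crown$normals)) crown <- estimate_normals(crown, 10)
  mn <- colMeans(crown$normals)
  if (sqrt(sum(mn^2)) > 0.2) return(mn / sqrt(sum(mn^2)))
  ax <- pca_frame(crown)$axes[3, ]
  pr <- as.numeric(pulp$points %*% ax)
  sk <- mean((pr - mean(pr))^3) / (sd(pr)^3 + 1e-12)
  if (sk < 0) ax <- -ax
  ax
}

#' Register a scan crown onto CBCT crown + pulp by PHMSR
#'
#' The pulp-horn mapping-surface registration pipeline: estimate crown
#' CBCT normals, extract pulp-horn feature directions, select mapping
#' points whose normals align with a horn direction within `gamma_max`,
#' then iterate point-to-surface correspondence search (local MLS quadric
#' patches around mapping points, dense grid samples as matching targets)
#' with the sparse lp ADMM pose solver until the incremental motion falls
#' below `rot_tol_deg` / `trans_tol_mm`.
#'
#' Presets resolve the printed defaults: small initial deviation uses
#' `gamma_max = 20` degrees and `r = 0.1` mm, large uses 25 degrees and
#' 0.3 mm; the solver runs `p = 0.5`, `mu = 10`, `n2 = 2`, `ns = 3`.
#'
#' @param scan_crown free [point_cloud()] (intraoral scan crown).
#' @param cbct_crown fixed [point_cloud()] (CBCT equivalent crown).
#' @param pulp CBCT pulp [point_cloud()] in the same frame as the crown.
#' @param deviation_preset `"small"` or `"large"`.
#' @param config optional [run_config()]; individual arguments below
#'   override it.
#' @param gamma_max,fit_radius,sample_radius,span,k_y,k_c,p,mu,n2,ns,surface_weight
#'   explicit parameter overrides (see [run_config()]).
#' @param n_horns,occlusal_axis pulp-horn extraction settings.
#' @param horns optional precomputed list of [pulp_horn_feature()].
#' @param surface_matching set `FALSE` to force point-point matching
#'   everywhere (diagnostic mode; the loop then reduces to sparse ICP).
#' @param trim_factor correspondence gate: pairs whose matched distance
#'   exceeds `trim_factor` times the median matched distance are dropped
#'   from the pose solve (robustness to dropout holes and gross outliers;
#'   `Inf` disables).
#' @param max_outer_iter,rot_tol_deg,trans_tol_mm outer-loop controls.
#' @param normal_k neighbour count for normal estimation.
#' @return a [registration_result()]; `transform` maps scan coordinates
#'   into the CBCT frame.
#' @export
register_phmsr <- function(scan_crown, cbct_crown, pulp,
                           deviation_preset = c("small", "large"),
                           config = NULL,
                           gamma_max = NULL, fit_radius = NULL,
                           sample_radius = NULL, span = NULL,
                           k_y = NULL, k_c = NULL,
                           p = NULL, mu = NULL, n2 = NULL, ns = NULL,
                           surface_weight = NULL,
                           n_horns = 4, occlusal_axis = NULL, horns = NULL,
                           surface_matching = TRUE, trim_factor = NULL,
                           max_outer_iter = 150, rot_tol_deg = 0.005,
                           trans_tol_mm = 1e-3, normal_k = 10) {
  deviation_preset <- match.arg(deviation_preset)
  cfg <- if (is.null(config)) run_config(method = "phmsr",
                                         deviation_preset = deviation_preset)
         else config
  ov <- list(gamma_max = gamma_max, fit_radius = fit_radius,
             sample_radius = sample_radius, span = span, k_y = k_y,
             k_c = k_c, p = p, mu = mu, n2 = n2, ns = ns,
             surface_weight = surface_weight)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) cfg[[nm]] <- ov[[nm]]
  if (!is.null(trim_factor)) cfg$trim_factor <- trim_factor
  if (is.null(cfg$span)) cfg$span <- cfg$fit_radius / 3

  if (is.null(cbct_crown$normals))
    cbct_crown <- estimate_normals(cbct_crown, k = normal_k)
  if (is.null(occlusal_axis))
    occlusal_axis <- estimate_occlusal_axis(cbct_crown, pulp)
  if (is.null(horns))
    horns <- pulp_horn_feature_directions(pulp, occlusal_axis, n_horns)
  eligible <- if (surface_matching) {
    sel <- phfm_select_mapping_points(cbct_crown, horns, cfg$gamma_max)
    mapping_eligibility(cbct_crown$points, sel$indices, cfg$k_y)
  } else {
    logical(n_points(cbct_crown))
  }

  tf <- rigid_transform()
  diag_rows <- list()
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_outer_iter)) {
    # each of the n2 Step-2 blocks re-matches at the current intermediate
    # pose: the matching targets are refreshed between solver blocks,
    # which shortens the path to the aligned pose
    inc_tot <- rigid_transform()
    n_surf <- 0L
    res_rmse <- NA_real_
    for (i2 in seq_len(cfg$n2)) {
      cur <- sweep(scan_crown$points %*% t(tf$rotation), 2, tf$translation, "+")
      mres <- cpp_match_correspondences(cbct_crown$points, cur, eligible,
                                        as.integer(cfg$k_c), cfg$fit_radius,
                                        cfg$sample_radius, cfg$span)
      d <- sqrt(rowSums((mres$matched - cur)^2))
      keep <- d <= cfg$trim_factor * stats::median(d)
      if (sum(keep) < 3) keep <- rep(TRUE, length(keep))
      corr <- correspondence_set(mres$matched[keep, , drop = FALSE],
                                 cur[keep, , drop = FALSE], "point_surface")
      w <- 1 + (mres$flag[keep] == 1) * (cfg$surface_weight - 1)
      st <- sparse_icp_state(p = cfg$p, mu = cfg$mu, n2 = 1, ns = cfg$ns)
      sol <- admm_sparse_solve(corr, st, weights = w)
      inc <- sol$transform
      tf <- compose_transform(inc, tf)
      inc_tot <- compose_transform(inc, inc_tot)
      n_surf <- sum(mres$flag == 1)
      res_rmse <- sqrt(mean(rowSums((sweep(corr$source %*% t(inc$rotation), 2,
                                           inc$translation, "+") - corr$target)^2)))
    }
    rot_inc <- rotation_angle_deg(inc_tot$rotation)
    # incremental motion measured at the current cloud centroid
    ctr <- colMeans(scan_crown$points)
    trans_inc <- sqrt(sum((as.numeric(inc_tot$rotation %*% ctr) +
                             inc_tot$translation - ctr)^2))
    diag_rows[[it]] <- data.frame(iter = it, rmse = res_rmse,
                                  rot_increment_deg = rot_inc,
                                  trans_increment_mm = trans_inc,
                                  n_surface = n_surf)
    if (rot_inc < rot_tol_deg && trans_inc < trans_tol_mm) {
      converged <- TRUE
      break
    }
  }
  # mapping-surface refinement: polish the pose on the surface-matched
  # correspondences alone — the limiting case of the mapped-point
  # weighting, driven purely by the feature regions' normal-direction
  # signal
  if (surface_matching) {
    for (it2 in seq_len(max_outer_iter)) {
      cur <- sweep(scan_crown$points %*% t(tf$rotation), 2, tf$translation, "+")
      mres <- cpp_match_correspondences(cbct_crown$points, cur, eligible,
                                        as.integer(cfg$k_c), cfg$fit_radius,
                                        cfg$sample_radius, cfg$span)
      s <- mres$flag == 1
      if (sum(s) < 50) break
      ms <- mres$matched[s, , drop = FALSE]
      cs <- cur[s, , drop = FALSE]
      d <- sqrt(rowSums((ms - cs)^2))
      keep <- d <= cfg$trim_factor * stats::median(d)
      if (sum(keep) < 3) break
      corr <- correspondence_set(ms[keep, , drop = FALSE],
                                 cs[keep, , drop = FALSE], "point_surface")
      st <- sparse_icp_state(p = cfg$p, mu = cfg$mu, n2 = cfg$n2, ns = cfg$ns)
      inc <- admm_sparse_solve(corr, st)$transform
      tf <- compose_transform(inc, tf)
      if (rotation_angle_deg(inc$rotation) < rot_tol_deg / 2) break
    }
  }
  registration_result(tf, "phmsr", it, converged,
                      do.call(rbind, diag_rows), cfg)
}
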