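# Registration accuracy metrics: crown RMSE (nearest-neighbour root mean
# square), and the crown-pulp position/orientation deviations (CPPD/CPOD)
# built on PCA frames of the crown and pulp clouds.

#' Crown registration RMSE
#'
#' For every point `c_h` of the fixed CBCT crown cloud, take its nearest
#' neighbour `y_h` in the registered scan cloud and return
#' `sqrt(mean(|c_h - y_h|^2))`. Smaller is better; this scores crown
#' surface agreement only, not the crown-pulp pose.
#'
#' @param cbct_crown fixed [point_cloud()].
#' @param registered_scan registered free [point_cloud()].
#' @return RMSE in mm.
#' @export
cloud_rmse <- function(cbct_crown, registered_scan) {
  if (!n_points(cbct_crown) || !n_points(registered_scan))
    stop("clouds must be non-empty")
  nn <- cpp_nn1(registered_scan$points, cbct_crown$points)
  sqrt(mean(nn$dist^2))
}

# ZYX intrinsic Euler angles (degrees) of a rotation matrix:
# R = Rz(alpha) Ry(beta) Rx(gamma)
euler_zyx_deg <- function(R) {
  beta <- asin(pmin(1, pmax(-1, -R[3, 1])))
  alpha <- atan2(R[2, 1], R[1, 1])
  gamma <- atan2(R[3, 2], R[3, 3])
  c(alpha, beta, gamma) * 180 / pi
}

# wrap angle differences into (-180, 180]
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Crown-pulp pose deviation (CPPD / CPOD)
#'
#' Measures how much the registered crown pose deviates, relative to the
#' pulp, from the theoretical (ground-truth) crown pose. PCA frames are
#' built for the pulp, the truth-pose crown and the registered crown; the
#' per-axis position deviations are the components (in the pulp frame) of
#' the difference between the actual and theoretical crown-pulp offsets,
#' and the per-axis orientation deviations are the differences of the ZYX
#' intrinsic Euler angles of each crown frame expressed relative to the
#' pulp frame. CPPD and CPOD are the Euclidean norms of those two
#' 3-vectors (mm and degrees).
#'
#' @param pulp CBCT pulp [point_cloud()].
#' @param crown_truth_pose the crown cloud in its theoretical pose.
#' @param crown_registered the same crown cloud in its registered pose.
#' @return object of class `pose_deviation` with `cppd`, `cpod`,
#'   `per_axis_position`, `per_axis_orientation`.
#' @export
crown_pulp_deviation <- function(pulp, crown_truth_pose, crown_registered) {
  fp <- pca_frame(pulp)
  fc_t <- pca_frame(crown_truth_pose)
  fc_a <- pca_frame(crown_registered)
  Rp <- t(fp$axes)    # columns = pulp axes in global coords
  Rt <- t(fc_t$axes)
  Ra <- t(fc_a$axes)
  # position: (O_p - O_c) - (O_p - O'_c) = O'_c - O_c, in pulp axes
  dpos <- as.numeric(fp$axes %*% (fc_a$origin - fc_t$origin))
  e_t <- euler_zyx_deg(t(Rp) %*% Rt)
  e_a <- euler_zyx_deg(t(Rp) %*% Ra)
  dori <- wrap_deg(e_a - e_t)
  structure(list(cppd = sqrt(sum(dpos^2)),
                 cpod = sqrt(sum(dori^2)),
                 per_axis_position = dpos,
                 per_axis_orientation = dori),
            class = "pose_deviation")
}

#' @export
print.pose_deviation <- function(x, ...) {
  cat(sprintf("<pose_deviation> CPPD %.4f mm, CPOD %.4f deg\n", x$cppd, x$cpod))
  invisible(x)
}

#' Rotation / translation error of a transform against ground truth
#'
#' Rotation error is the angle of `R_est R_truth^T`; translation error is
#' the displacement between the two transforms' images of `ref_point`
#' (defaults to the origin), which avoids conflating the raw translation
#' vectors with rotation lever arms.
#'
#' @param est,truth [rigid_transform()] objects.
#' @param ref_point point (mm) at which the displacement is measured,
#'   typically the source-cloud centroid.
#' @return list with `rot_deg` and `trans_mm`.
#' @export
transform_error <- function(est, truth, ref_point = c(0, 0, 0)) {
  rot <- rotation_angle_deg(est$rotation %*% t(truth$rotation))
  pe <- as.numeric(est$rotation %*% ref_point) + est$translation
  pt <- as.numeric(truth$rotation %*% ref_point) + truth$translation
  list(rot_deg = rot, trans_mm = sqrt(sum((pe - pt)^2)))
}

#' Evaluate one registration run
#'
#' Method-agnostic harness row: applies the estimated (and, when
#' available, the ground-truth) transform to the free cloud and reports
#' RMSE, CPPD, CPOD plus the transform-recovery errors. Without a ground
#' truth the crown-pulp metrics are `NA` and RMSE is still reported.
#'
#' @param result a [registration_result()].
#' @param clouds list with elements `scan` (free cloud in its initial
#'   pose), `cbct_crown`, `pulp`.
#' @param truth optional ground-truth [rigid_transform()].
#' @param seed,preset bookkeeping columns.
#' @return one-row `data.frame` with columns `method`, `preset`, `seed`,
#'   `rmse`, `cppd`, `cpod`, `rot_error_deg`, `trans_error_mm`,
#'   `iterations`, `converged`.
#' @export
evaluate_run <- function(result, clouds, truth = NULL, seed = NA, preset = NA) {
  reg <- apply_transform(clouds$scan, result$transform)
  r <- cloud_rmse(clouds$cbct_crown, reg)
  cppd <- cpod <- rot_e <- trans_e <- NA_real_
  if (!is.null(truth)) {
    tru <- apply_transform(clouds$scan, truth)
    dev <- crown_pulp_deviation(clouds$pulp, tru, reg)
    cppd <- dev$cppd; cpod <- dev$cpod
    te <- transform_error(result$transform, truth,
                          ref_point = colMeans(clouds$scan$points))
    rot_e <- te$rot_deg; trans_e <- te$trans_mm
  }
  data.frame(method = result$method, preset = preset, seed = seed,
             rmse = r, cppd = cppd, cpod = cpod,
             rot_error_deg = rot_e, trans_error_mm = trans_e,
             iterations = result$iterations, converged = result$converged,
             stringsAsFactors = FALSE)
}

#' Summarise a batch of evaluation rows
#'
#' Mean and standard deviation of each metric per method and preset; the
#' layout used when averaging repeated registrations of one subject.
#'
#' @param rows data frame of [evaluate_run()] rows.
#' @return data frame with one row per method x preset.
#' @export
summarize_runs <- function(rows) {
  sp <- split(rows, interaction(rows$method, rows$preset, drop = TRUE))
  out <- lapply(sp, function(g) {
    data.frame(method = g$method[1], preset = g$preset[1], n = nrow(g),
               rmse_mean = mean(g$rmse), rmse_sd = sd(g$rmse),
               cppd_mean = mean(g$cppd), cppd_sd = sd(g$cppd),
               cpod_mean = mean(g$cpod), cpod_sd = sd(g$cpod),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
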