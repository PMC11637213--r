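# Comparison baselines: classic ICP, point-point sparse ICP (same ADMM
# solver as the mapping-surface method, plain nearest-neighbour
# correspondences), and rigid coherent point drift.

#' Classic ICP registration
#'
#' Nearest-neighbour correspondences plus the closed-form SVD pose update
#' per iteration; stops when the mean residual changes by less than
#' `tol_mm` (the printed allowable error, 0.1 mm) or at `max_iter`
#' iterations (printed default 100).
#'
#' @param source free [point_cloud()].
#' @param target fixed [point_cloud()].
#' @param max_iter iteration cap.
#' @param tol_mm mean-residual change tolerance (mm).
#' @return a [registration_result()].
#' @export
icp_register <- function(source, target, max_iter = 100, tol_mm = 0.1) {
  check_registration_inputs(source, target)
  tf <- rigid_transform()
  prev <- Inf
  diag_rows <- list()
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    cur <- sweep(source$points %*% t(tf$rotation), 2, tf$translation, "+")
    nn <- cpp_nn1(target$points, cur)
    matched <- target$points[nn$index, , drop = FALSE]
    inc <- kabsch(cur, matched)
    tf <- compose_transform(inc, tf)
    res <- mean(nn$dist)
    diag_rows[[it]] <- data.frame(iter = it, mean_residual = res)
    if (abs(prev - res) < tol_mm) { converged <- TRUE; break }
    prev <- res
  }
  registration_result(tf, "icp", it, converged, do.call(rbind, diag_rows),
                      list(max_iter = max_iter, tol_mm = tol_mm))
}

#' Sparse ICP registration (point-point)
#'
#' The same lp ADMM solver as the mapping-surface method but with plain
#' nearest-neighbour correspondences — no pulp-horn mapping, no surfaces.
#' Printed defaults: `p = 0.5`, `mu = 10`, `n2 = 2`, `ns = 3`.
#'
#' @param source free [point_cloud()].
#' @param target fixed [point_cloud()].
#' @param p,mu,n2,ns solver settings (see [sparse_icp_state()]).
#' @param max_outer_iter,rot_tol_deg,trans_tol_mm outer-loop controls.
#' @return a [registration_result()].
#' @export
sparse_icp_register <- function(source, target, p = 0.5, mu = 10, n2 = 2,
                                ns = 3, max_outer_iter = 50,
                                rot_tol_deg = 0.01, trans_tol_mm = 1e-3) {
  check_registration_inputs(source, target)
  tf <- rigid_transform()
  diag_rows <- list()
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_outer_iter)) {
    cur <- sweep(source$points %*% t(tf$rotation), 2, tf$translation, "+")
    nn <- cpp_nn1(target$points, cur)
    corr <- correspondence_set(target$points[nn$index, , drop = FALSE], cur)
    sol <- admm_sparse_solve(corr, sparse_icp_state(p, mu, n2, ns))
    inc <- sol$transform
    tf <- compose_transform(inc, tf)
    rot_inc <- rotation_angle_deg(inc$rotation)
    ctr <- colMeans(cur)
    trans_inc <- sqrt(sum((as.numeric(inc$rotation %*% ctr) + inc$translation - ctr)^2))
    diag_rows[[it]] <- data.frame(iter = it, mean_residual = mean(nn$dist),
                                  rot_increment_deg = rot_inc,
                                  trans_increment_mm = trans_inc)
    if (rot_inc < rot_tol_deg && trans_inc < trans_tol_mm) {
      converged <- TRUE; break
    }
  }
  registration_result(tf, "sparse_icp", it, converged,
                      do.call(rbind, diag_rows),
                      list(p = p, mu = mu, n2 = n2, ns = ns))
}

#' Rigid coherent point drift registration
#'
#' Expectation-maximisation over a Gaussian mixture whose centroids are
#' the (rigidly moved) source points, with an isotropic variance shared by
#' all components and a uniform outlier component of weight
#' `outlier_weight`. The M-step pose update is the closed-form SVD solve;
#' iteration stops when the negative log-likelihood changes by less than
#' `tol` or the variance underflows.
#'
#' @param source free [point_cloud()].
#' @param target fixed [point_cloud()].
#' @param outlier_weight uniform-component weight in `[0, 1)`.
#' @param max_iter EM iteration cap.
#' @param tol log-likelihood change tolerance.
#' @return a [registration_result()]; diagnostics carry the negative
#'   log-likelihood trajectory.
#' @export
cpd_rigid_register <- function(source, target, outlier_weight = 0.1,
                               max_iter = 60, tol = 1e-6) {
  if (!n_points(source) || !n_points(target)) stop("clouds must be non-empty")
  X <- target$points   # N x 3
  Y0 <- source$points  # M x 3
  N <- nrow(X); M <- nrow(Y0)
  tf <- rigid_transform()
  Yc <- Y0
  sigma2 <- (N * sum(colSums(Y0^2)) + M * sum(colSums(X^2)) -
               2 * sum(colSums(X) * colSums(Y0))) / (3 * N * M)
  prev_nll <- Inf
  diag_rows <- list()
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    e <- cpp_cpd_estep(X, Yc, sigma2, outlier_weight)
    nll <- e$nll
    diag_rows[[it]] <- data.frame(iter = it, nll = nll, sigma2 = sigma2)
    if (is.finite(prev_nll) && abs(prev_nll - nll) < tol) { converged <- TRUE; break }
    prev_nll <- nll
    Np <- sum(e$P1)
    if (Np < 1e-12) { converged <- TRUE; break }
    mu_x <- as.numeric(t(X) %*% e$Pt1) / Np
    mu_y <- as.numeric(t(Y0) %*% e$P1) / Np
    A <- t(e$PX) %*% Y0 - Np * (mu_x %o% mu_y)
    sv <- svd(A)
    Csgn <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
    R <- sv$u %*% Csgn %*% t(sv$v)
    tr_ <- mu_x - as.numeric(R %*% mu_y)
    tf <- rigid_transform(R, tr_)
    Yc <- sweep(Y0 %*% t(R), 2, tr_, "+")
    xc2 <- sum(e$Pt1 * rowSums(sweep(X, 2, mu_x)^2))
    yc2 <- sum(e$P1 * rowSums(sweep(Y0, 2, mu_y)^2))
    sigma2 <- (xc2 + yc2 - 2 * sum(diag(t(A) %*% R))) / (3 * Np)
    if (!is.finite(sigma2) || sigma2 < 1e-10) { sigma2 <- 1e-10; converged <- TRUE; break }
  }
  registration_result(tf, "cpd", it, converged, do.call(rbind, diag_rows),
                      list(outlier_weight = outlier_weight,
                           max_iter = max_iter, tol = tol))
}

check_registration_inputs <- function(source, target) {
  if (n_points(source) < 3 || n_points(target) < 3)
    stop("both clouds need at least 3 points")
  if (qr(sweep(source$points, 2, colMeans(source$points)))$rank < 2)
    stop("degenerate geometry: source points are collinear")
  invisible(TRUE)
}
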