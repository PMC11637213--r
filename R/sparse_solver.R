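# The lp sparse alignment solver: correspondence sets, the proximal
# shrinkage of ||z||_2^p, the weighted Procrustes pose update, and the
# ADMM alternation that combines them.

#' Construct a correspondence set
#'
#' Pairs of a matched target point `c'_h` and a free source point `y_h`,
#' the unit the pose solver consumes.
#'
#' @param target m x 3 matrix of matched target points.
#' @param source m x 3 matrix of the free points they correspond to.
#' @param mode `"point_point"` or `"point_surface"` (bookkeeping only).
#' @return object of class `correspondence_set`.
#' @export
correspondence_set <- function(target, source,
                               mode = c("point_point", "point_surface")) {
  mode <- match.arg(mode)
  target <- as_xyz_matrix(target, "target")
  source <- as_xyz_matrix(source, "source")
  if (nrow(target) != nrow(source)) stop("target and source must pair one-to-one")
  if (!all(is.finite(target))) stop("target points must be finite")
  structure(list(target = target, source = source, mode = mode),
            class = "correspondence_set")
}

#' Construct the sparse-ICP solver state
#'
#' @param p sparsity exponent of the residual norm (0 < p <= 2; the
#'   printed default is 0.5).
#' @param mu ADMM penalty weight (> 0; default 10).
#' @param n2 Step-2 iteration count (default 2).
#' @param ns inner convergence passes per Step-2 iteration (default 3).
#' @return object of class `sparse_icp_state`.
#' @export
sparse_icp_state <- function(p = 0.5, mu = 10, n2 = 2, ns = 3) {
  if (p <= 0 || p > 2) stop("p must be in (0, 2]")
  if (mu <= 0) stop("mu must be positive")
  structure(list(p = p, mu = mu, n2 = as.integer(n2), ns = as.integer(ns),
                 Z = NULL, Lambda = NULL),
            class = "sparse_icp_state")
}

# proximal operator of ||z||_2^p / mu at v (row-wise on m x 3 residuals):
# argmin_z ||z||^p + mu/2 ||z - v||^2. Closed form for p = 2 and p = 1;
# Newton scalar solve on the magnitude for p < 1. `mu` may be a vector
# (per-correspondence penalty, used for weighted correspondences).
prox_lp <- function(V, p, mu) {
  a <- sqrt(rowSums(V^2))
  mu <- rep_len(mu, length(a))
  s <- numeric(length(a))
  if (p == 2) {
    s <- mu * a / (mu + 2)
  } else if (p == 1) {
    s <- pmax(a - 1 / mu, 0)
  } else {
    # existence threshold: min over s>0 of p s^(p-1) + mu s
    sstar <- (p * (1 - p) / mu)^(1 / (2 - p))
    thresh <- (p * sstar^(p - 1) + mu * sstar) / mu
    for (i in which(a > thresh)) {
      ai <- a[i]; mui <- mu[i]
      si <- ai
      for (it in 1:30) {
        g <- p * si^(p - 1) + mui * (si - ai)
        gp <- p * (p - 1) * si^(p - 2) + mui
        step <- g / gp
        si <- si - step
        if (si <= 0) { si <- 1e-12 }
        if (abs(step) < 1e-12) break
      }
      # keep the root only if it beats the z = 0 objective
      if (si^p + mui / 2 * (si - ai)^2 < mui / 2 * ai^2) s[i] <- si
    }
  }
  scale <- ifelse(a > 0, s / a, 0)
  V * scale
}

# weighted Procrustes/Kabsch: rigid transform mapping source onto target
kabsch <- function(source, target, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(source))
  w <- weights / sum(weights)
  mu_s <- colSums(source * w)
  mu_t <- colSums(target * w)
  S <- sweep(source, 2, mu_s)
  T_ <- sweep(target, 2, mu_t)
  H <- t(S * w) %*% T_
  sv <- svd(H)
  d <- det(sv$v %*% t(sv$u))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, mu_t - as.numeric(R %*% mu_s))
}

#' Solve a correspondence set by sparse-ICP ADMM
#'
#' Minimises the lp norm of the residuals `R y_h + t - c'_h` via the
#' alternating direction method of multipliers: (i) a z-update, the
#' proximal shrinkage of `||z||_2^p` applied to each shifted residual;
#' (ii) an R,t-update, a closed-form SVD Procrustes solve against the
#' ADMM-shifted targets; and (iii) the multiplier ascent
#' `lambda_h <- lambda_h + mu * delta_h` after each Step-2 iteration.
#' Each Step-2 iteration runs `ns` inner (z, R,t) passes at fixed
#' multipliers, over which the augmented Lagrangian is non-increasing.
#'
#' Residuals are measured on unit-normalised coordinates (both clouds
#' divided by the target's circumscribed diameter before solving, and the
#' translation rescaled after), the convention of reference sparse-ICP
#' implementations; the `p` and `mu` defaults assume it, since the
#' proximal shrinkage threshold is scale-dependent. The diameter is
#' rotation-invariant, so the solve commutes with a common rigid motion
#' of both clouds. Set `normalize = FALSE` to solve on raw coordinates.
#'
#' @param corr a [correspondence_set()].
#' @param state a [sparse_icp_state()].
#' @param init optional initial [rigid_transform()].
#' @param normalize solve on unit-normalised coordinates (default).
#' @param weights optional per-correspondence weights (>= 0); a weight
#'   `w_h` multiplies that pair's residual term, raising its influence in
#'   both the pose solve and the shrinkage (the mapped points and their
#'   neighbours get increased weight in the registration).
#' @return list with `transform`, the updated `state`, and `objective`
#'   (augmented-Lagrangian trace on the solver's coordinate scale, one
#'   value per inner pass).
#' @export
admm_sparse_solve <- function(corr, state = sparse_icp_state(), init = NULL,
                              normalize = TRUE, weights = NULL) {
  stopifnot(inherits(corr, "correspondence_set"),
            inherits(state, "sparse_icp_state"))
  m <- nrow(corr$source)
  if (m < 3) stop("need at least 3 correspondences")
  if (qr(sweep(corr$source, 2, colMeans(corr$source)))$rank < 2)
    stop("degenerate correspondence geometry (collinear points)")
  scale <- 1
  if (normalize) {
    # circumscribed diameter of the target: rotation-invariant, so the
    # solve commutes exactly with a common rigid motion of both clouds
    ctr <- colMeans(corr$target)
    scale <- 2 * sqrt(max(rowSums(sweep(corr$target, 2, ctr)^2)))
    if (!is.finite(scale) || scale <= 0) scale <- 1
  }
  src <- corr$source / scale
  tgt <- corr$target / scale
  tf <- if (is.null(init))
    rigid_transform()
  else
    rigid_transform(init$rotation, init$translation / scale)
  Z <- if (is.null(state$Z)) matrix(0, m, 3) else state$Z
  Lam <- if (is.null(state$Lambda)) matrix(0, m, 3) else state$Lambda
  mu <- state$mu; p <- state$p
  w <- if (is.null(weights)) rep(1, m) else rep_len(as.numeric(weights), m)
  muw <- mu * w
  obj <- numeric(0)
  resid <- function(tf) {
    sweep(src %*% t(tf$rotation), 2, tf$translation, "+") - tgt
  }
  for (i2 in seq_len(state$n2)) {
    for (s in seq_len(state$ns)) {
      r <- resid(tf)
      Z <- prox_lp(r + Lam / muw, p, muw)
      shift_target <- tgt + Z - Lam / muw
      tf <- kabsch(src, shift_target, w)
      r <- resid(tf)
      delta <- r - Z
      obj <- c(obj, sum(rowSums(Z^2)^(p / 2)) + sum(Lam * delta) +
                 sum(muw / 2 * rowSums(delta^2)))
    }
    delta <- resid(tf) - Z
    Lam <- Lam + muw * delta
  }
  state$Z <- Z
  state$Lambda <- Lam
  list(transform = rigid_transform(tf$rotation, tf$translation * scale),
       state = state, objective = obj)
}
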