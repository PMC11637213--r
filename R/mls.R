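# Pulp-horn feature mapping and moving-least-squares mapping surfaces:
# selection of the crown CBCT points whose normals align with pulp-horn
# feature directions, local quadric patches around those points, and the
# point-to-surface correspondence search.

#' Construct a pulp-horn feature
#'
#' @param apex horn apex (mm).
#' @param direction unit feature direction.
#' @param source `"automatic"` or `"manual"`.
#' @return an object of class `pulp_horn_feature`.
#' @export
pulp_horn_feature <- function(apex, direction, source = c("automatic", "manual")) {
  source <- match.arg(source)
  direction <- as.numeric(direction)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(apex = as.numeric(apex), direction = direction, source = source),
            class = "pulp_horn_feature")
}

#' Pulp-horn feature directions
#'
#' The pulp horns are the apical extensions of the pulp chamber toward the
#' cusps and carry most of the pulp's pose information. Automatic mode
#' finds the `n_horns` highest pulp-surface points along the occlusal axis
#' that are local maxima within `min_separation` and at least
#' `min_separation` apart; each horn's feature direction is the unit
#' vector from the pulp centroid to its apex. Manual overrides pass
#' through verbatim (horn picking is commonly done interactively).
#'
#' @param pulp a [point_cloud()] of the CBCT pulp.
#' @param occlusal_axis unit vector pointing toward the biting surface.
#' @param n_horns number of horns expected (molars have four).
#' @param min_separation minimum apex spacing in mm.
#' @param manual_overrides optional list of [pulp_horn_feature()] objects;
#'   returned unchanged when supplied.
#' @return list of [pulp_horn_feature()] objects.
#' @export
pulp_horn_feature_directions <- function(pulp, occlusal_axis = c(0, 0, 1),
                                         n_horns = 4, min_separation = 1,
                                         manual_overrides = NULL) {
  if (!is.null(manual_overrides)) {
    stopifnot(all(vapply(manual_overrides, inherits, TRUE, "pulp_horn_feature")))
    return(manual_overrides)
  }
  if (!n_points(pulp)) stop("pulp cloud is empty")
  if (n_horns < 1) stop("n_horns must be >= 1")
  u <- occlusal_axis / sqrt(sum(occlusal_axis^2))
  h <- as.numeric(pulp$points %*% u)
  ctr <- colMeans(pulp$points)
  ord <- order(h, decreasing = TRUE)
  apexes <- integer(0)
  for (i in ord) {
    if (length(apexes) == n_horns) break
    p <- pulp$points[i, ]
    if (length(apexes)) {
      d <- sqrt(colSums((t(pulp$points[apexes, , drop = FALSE]) - p)^2))
      if (any(d < min_separation)) next
    }
    # local maximum along the axis within the separation radius
    d_all <- sqrt(colSums((t(pulp$points) - p)^2))
    nb <- d_all < min_separation
    if (any(h[nb] > h[i] + 1e-9)) next
    apexes <- c(apexes, i)
  }
  if (length(apexes) < n_horns)
    stop(sprintf("found only %d well-separated pulp-horn maxima (need %d)",
                 length(apexes), n_horns))
  lapply(apexes, function(i) {
    a <- pulp$points[i, ]
    pulp_horn_feature(a, a - ctr, "automatic")
  })
}

#' Pulp-horn feature mapping (PHFM) of the crown CBCT cloud
#'
#' A crown point is retained as a mapping point when the angle between its
#' surface normal and the closest pulp-horn feature direction is at most
#' `gamma_max` degrees. The retained indices are the centres around which
#' mapping surfaces are reconstructed during registration; enlarging
#' `gamma_max` retains more points, which suits larger initial deviations.
#'
#' @param cbct_crown a [point_cloud()] with normals.
#' @param horns list of [pulp_horn_feature()] objects.
#' @param gamma_max angle threshold in degrees (0..180).
#' @return list of class `mapping_selection` with `indices`, `gamma_max`,
#'   and the per-point best horn `angles` (degrees).
#' @export
phfm_select_mapping_points <- function(cbct_crown, horns, gamma_max) {
  if (is.null(cbct_crown$normals)) stop("crown cloud needs normals; run estimate_normals()")
  if (gamma_max < 0 || gamma_max > 180) stop("gamma_max must be in [0, 180]")
  dirs <- t(vapply(horns, function(hh) hh$direction, numeric(3)))
  ca <- cbct_crown$normals %*% t(dirs)          # n x n_horns cosines
  ca[ca > 1] <- 1; ca[ca < -1] <- -1
  ang <- acos(ca) * 180 / pi
  best <- apply(ang, 1, min)
  idx <- which(best <= gamma_max)
  if (!length(idx))
    stop("no mapping points retained; increase gamma_max")
  structure(list(indices = idx, gamma_max = gamma_max, angles = best),
            class = "mapping_selection")
}

#' Fit a moving-least-squares quadric patch
#'
#' Builds the local mapping surface at a crown CBCT point: a tangent-plane
#' frame from the PCA of the `k_c`-nearest neighbourhood, then a weighted
#' least-squares quadric `z' = a0 + a1 x' + a2 y' + a3 x'^2 + a4 x'y' +
#' a5 y'^2` with Gaussian weights `exp(-(d/h)^2)`, `h = fit_radius / 2`.
#' The fit radius thus controls how far neighbours influence the surface;
#' shrinking it degenerates the patch toward the centre point. Fewer than
#' 6 usable neighbours flags the patch for point-point fallback rather
#' than failing.
#'
#' @param cbct_crown a [point_cloud()].
#' @param center_index index of the patch centre.
#' @param fit_radius Gaussian bandwidth scale r (mm).
#' @param min_neighbors neighbourhood size `k_c` (>= 6; the registration
#'   defaults respect `k_c >= 3 k_y`).
#' @return object of class `local_surface_patch` with `ok`, `coeffs`,
#'   `origin`, `axes` (rows x', y', z'), `center_index`, `fit_radius`,
#'   `neighbors`; `ok = FALSE` marks the point-point fallback.
#' @export
fit_mls_patch <- function(cbct_crown, center_index, fit_radius,
                          min_neighbors = 24) {
  pts <- cloud_points(cbct_crown)
  if (center_index < 1 || center_index > nrow(pts)) stop("center_index out of range")
  res <- cpp_fit_patch(pts, as.integer(center_index), as.integer(min_neighbors),
                       fit_radius)
  structure(c(res, list(center_index = center_index, fit_radius = fit_radius)),
            class = "local_surface_patch")
}

#' Sample a fitted patch on a regular grid
#'
#' A grid of spacing `span` over the tangent-plane disk of radius
#' `sample_radius`, lifted onto the quadric; the dense samples are the
#' correspondence candidates of point-to-surface matching. When
#' `span > 2 * sample_radius` only the centre sample exists and a warning
#' is raised.
#'
#' @param patch a [fit_mls_patch()] result with `ok = TRUE`.
#' @param sample_radius disk radius r_s (mm).
#' @param span grid spacing d_s (mm).
#' @return the patch with a `samples` matrix added.
#' @export
sample_patch <- function(patch, sample_radius, span) {
  stopifnot(inherits(patch, "local_surface_patch"))
  if (!isTRUE(patch$ok)) stop("cannot sample a fallback patch")
  if (span <= 0 || sample_radius <= 0) stop("span and sample_radius must be positive")
  if (span > 2 * sample_radius)
    warning("span exceeds the patch diameter; returning the single centre sample")
  s <- cpp_patch_samples(patch$coeffs, patch$origin, patch$axes,
                         sample_radius, span)
  patch$samples <- s
  patch$sample_radius <- sample_radius
  patch$span <- span
  patch
}

#' Match one free point to the mapping surface
#'
#' The correspondence rule of the registration: find the nearest crown
#' CBCT point `c_h` to the free point; if `c_h` lies in (the
#' `k_y`-neighbourhood of) the mapping selection, fit and sample a local
#' quadric from its `k_c`-neighbourhood and return the nearest patch
#' sample `c'_h`; otherwise — or when the patch fit falls back — return
#' `c_h` itself (point-point matching).
#'
#' @param free_point length-3 free (scan) point.
#' @param cbct_crown target [point_cloud()].
#' @param selection a [phfm_select_mapping_points()] result.
#' @param k_y,k_c neighbourhood sizes (`k_c >= 3 k_y`).
#' @param fit_radius,sample_radius,span patch parameters (mm).
#' @return list with `target` (the matched point `c'_h`), `mode`
#'   (`"point_surface"` or `"point_point"`), `nn_index`.
#' @export
match_point_to_surface <- function(free_point, cbct_crown, selection,
                                   k_y = 8, k_c = 24,
                                   fit_radius = 0.1, sample_radius = 0.1,
                                   span = fit_radius / 3) {
  pts <- cloud_points(cbct_crown)
  eligible <- mapping_eligibility(pts, selection$indices, k_y)
  res <- cpp_match_correspondences(pts, matrix(as.numeric(free_point), 1, 3),
                                   eligible, as.integer(k_c),
                                   fit_radius, sample_radius, span)
  list(target = as.numeric(res$matched[1, ]),
       mode = if (res$flag[1] == 1) "point_surface" else "point_point",
       nn_index = res$nn_index[1])
}

# eligibility: a target index is eligible for surface matching when it is
# a mapping point or lies in the k_y-neighbourhood of one
mapping_eligibility <- function(pts, mapped_indices, k_y) {
  eligible <- logical(nrow(pts))
  eligible[mapped_indices] <- TRUE
  if (k_y > 0 && length(mapped_indices)) {
    k <- min(k_y, nrow(pts))
    nb <- cpp_knn(pts, pts[mapped_indices, , drop = FALSE], as.integer(k))
    eligible[as.integer(nb)] <- TRUE
  }
  eligible
}
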