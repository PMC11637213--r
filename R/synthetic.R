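# Synthetic tooth phantoms: a radially parameterised crown with occlusal
# cusps and a pulp with conical horns beneath them, plus generators for
# scan-like clouds, CBCT-like degraded clouds, pose perturbations, and
# segmentation phantom volumes. Every generator is a pure function of its
# parameters and seed.

with_seed <- function(seed, code) {
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

# radial surface value r(u) for unit directions u (n x 3): ellipsoid base
# (unequal mesiodistal/buccolingual/occlusal semi-axes — molar crowns are
# rhomboidal, not surfaces of revolution) modulated by Gaussian bumps of
# per-cusp amplitude around the cusp directions, and, for the crown, by
# occlusal developmental grooves midway between the cusps
radial_eval <- function(u, a, b, c, bump_dirs, bump_amp, bump_width, scale = 1,
                        groove_phi = NULL, groove_depth = 0) {
  r0 <- 1 / sqrt((u[, 1] / a)^2 + (u[, 2] / b)^2 + (u[, 3] / c)^2)
  if (nrow(bump_dirs)) {
    ca <- u %*% t(bump_dirs)
    ca[ca > 1] <- 1; ca[ca < -1] <- -1
    ang <- acos(ca)
    bump <- as.numeric(exp(-(ang / bump_width)^2) %*% bump_amp)
  } else bump <- 0
  groove <- 0
  if (groove_depth > 0 && length(groove_phi)) {
    phi <- atan2(u[, 2], u[, 1])
    theta <- acos(pmin(1, pmax(-1, u[, 3])))      # polar angle from occlusal
    occl <- exp(-(theta / 0.6)^2)                 # grooves live on the table
    g <- 0
    # groove half-width ~0.2 rad (~0.6 mm at the occlusal table): a real
    # fissure scale that the 0.25 mm CBCT voxel grid can still resolve
    for (gp in groove_phi) {
      dphi <- atan2(sin(phi - gp), cos(phi - gp))
      g <- g + exp(-(dphi / 0.2)^2)
    }
    groove <- groove_depth * pmin(g, 1) * occl
  }
  scale * r0 * (1 + bump - groove)
}

#' Generate a synthetic tooth phantom
#'
#' A molar-like crown — a flattened ellipsoid with `n_cusps` Gaussian
#' cusps on the occlusal face — enclosing a scaled-down pulp surface with
#' a conical horn beneath each cusp. The phantom is a radial surface, so
#' point containment and exact surface distances are available for every
#' downstream oracle. Horn and cusp apexes are recorded as ground truth.
#'
#' @param n_cusps number of cusps/horns (molars: 4).
#' @param crown_diameter_mm mesiodistal crown diameter (default 10 mm).
#' @param seed RNG seed (cusp azimuth jitter); same seed, same phantom.
#' @param cusp_height cusp bump amplitude (fraction of local radius).
#' @param horn_height pulp horn amplitude (fraction of local pulp radius).
#' @param pulp_scale pulp size relative to the crown.
#' @param groove_depth depth of the occlusal developmental grooves between
#'   cusps (fraction of local radius).
#' @param mesh_resolution c(n_polar, n_azimuth) grid of the triangulation.
#' @return object of class `tooth_phantom` with crown/pulp meshes
#'   (`*_vertices`, `*_faces`), `horn_apexes`, `cusp_apexes`,
#'   `occlusal_axis`, `margin_z`, `seed` and the radial parameters.
#' @export
make_tooth_phantom <- function(n_cusps = 4, crown_diameter_mm = 10, seed = 1,
                               cusp_height = 0.18, horn_height = 0.9,
                               pulp_scale = 0.45, groove_depth = 0.15,
                               mesh_resolution = c(48, 96)) {
  if (n_cusps < 1) stop("n_cusps must be >= 1")
  if (crown_diameter_mm <= 0) stop("crown diameter must be positive")
  a <- crown_diameter_mm / 2
  b <- 0.85 * a            # buccolingual width < mesiodistal (rhomboidal crown)
  c_ <- 0.7 * a
  with_seed(seed, {
    psi <- 2 * pi * (seq_len(n_cusps) - 1) / n_cusps +
      runif(n_cusps, -5, 5) * pi / 180
    amp_fac <- runif(n_cusps, 0.75, 1.25)   # cusps of unequal height
  })
  tau <- 40 * pi / 180
  dirs <- cbind(sin(tau) * cos(psi), sin(tau) * sin(psi), rep(cos(tau), n_cusps))
  crown_amp <- cusp_height * amp_fac
  pulp_amp <- horn_height * amp_fac
  groove_phi <- if (n_cusps > 1) psi[-n_cusps] + diff(psi) / 2 else numeric(0)
  pars <- list(a = a, b = b, c = c_, dirs = dirs,
               crown_amp = crown_amp, crown_width = 0.30,
               pulp_amp = pulp_amp, pulp_width = 0.15,
               pulp_scale = pulp_scale,
               groove_phi = groove_phi, groove_depth = groove_depth)
  r_crown <- function(u) radial_eval(u, a, b, c_, dirs, crown_amp, 0.30,
                                     groove_phi = groove_phi,
                                     groove_depth = groove_depth)
  r_pulp <- function(u) radial_eval(u, a, b, c_, dirs, pulp_amp, 0.15, pulp_scale)
  # feasibility: pulp strictly inside crown on a dense direction grid
  ug <- unit_sphere_grid(96, 192)
  if (any(r_pulp(ug) >= r_crown(ug)))
    stop("infeasible phantom: pulp surface would intersect the crown")
  crown <- radial_mesh(r_crown, mesh_resolution[1], mesh_resolution[2])
  pulp <- radial_mesh(r_pulp, mesh_resolution[1], mesh_resolution[2])
  # ground-truth apexes: highest surface point near each cusp direction
  apex_of <- function(rfun) {
    pts <- ug * rfun(ug)
    t(vapply(seq_len(nrow(dirs)), function(i) {
      near <- acos(pmin(1, ug %*% dirs[i, ])) < 0.45
      cand <- pts[near, , drop = FALSE]
      cand[which.max(cand[, 3]), ]
    }, numeric(3)))
  }
  structure(list(crown_vertices = crown$vertices, crown_faces = crown$faces,
                 pulp_vertices = pulp$vertices, pulp_faces = pulp$faces,
                 horn_apexes = apex_of(r_pulp),
                 cusp_apexes = apex_of(r_crown),
                 occlusal_axis = c(0, 0, 1),
                 margin_z = -0.2 * c_,
                 seed = seed, params = pars),
            class = "tooth_phantom")
}

#' @export
print.tooth_phantom <- function(x, ...) {
  cat(sprintf("<tooth_phantom> %d cusps, diameter %.1f mm, seed %d\n",
              nrow(x$params$dirs), 2 * x$params$a, x$seed))
  invisible(x)
}

unit_sphere_grid <- function(nth, nph) {
  th <- (seq_len(nth) - 0.5) / nth * pi
  ph <- (seq_len(nph) - 1) / nph * 2 * pi
  g <- expand.grid(th = th, ph = ph)
  cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
}

# closed UV-sphere triangulation of a radial surface
radial_mesh <- function(rfun, nth, nph) {
  th <- seq_len(nth - 1) / nth * pi  # interior rings
  ph <- (seq_len(nph) - 1) / nph * 2 * pi
  g <- expand.grid(ph = ph, th = th)
  u <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  u <- rbind(c(0, 0, 1), u, c(0, 0, -1))
  V <- u * rfun(u)
  idx <- function(i, j) 1 + (i - 1) * nph + ((j - 1) %% nph) + 1  # ring i, col j
  faces <- list()
  # top fan
  faces[[1]] <- cbind(1, idx(1, seq_len(nph)), idx(1, seq_len(nph) + 1))
  # bands
  if (nth > 2) {
    for (i in seq_len(nth - 2)) {
      j <- seq_len(nph)
      faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  bottom <- nrow(V)
  faces[[length(faces) + 1]] <- cbind(bottom, idx(nth - 1, seq_len(nph) + 1),
                                      idx(nth - 1, seq_len(nph)))
  F_ <- do.call(rbind, faces)
  storage.mode(F_) <- "integer"
  dimnames(F_) <- NULL
  list(vertices = V, faces = F_)
}

# approximate signed distance to a radial surface via the implicit
# function F(p) = |p| - r(p/|p|) and its numerical gradient
radial_sdf <- function(pts, rfun, grad = FALSE) {
  Fv <- function(p) {
    nrm <- sqrt(rowSums(p^2))
    nrm[nrm == 0] <- 1e-12
    nrm - rfun(p / nrm)
  }
  f <- Fv(pts)
  if (!grad) return(f)
  h <- 1e-5
  g <- matrix(0, nrow(pts), 3)
  for (j in 1:3) {
    e <- matrix(0, nrow(pts), 3); e[, j] <- h
    g[, j] <- (Fv(pts + e) - Fv(pts - e)) / (2 * h)
  }
  list(value = f, grad = g)
}

# signed distance to a radial surface: Newton-project each point onto the
# implicit surface F(p) = |p| - r(p/|p|) and measure the Euclidean
# displacement. More robust than the one-step F/|grad F| estimate, whose
# gradient is ill-conditioned near the occlusal axis where the grooves
# meet.
radial_distance <- function(pts, rfun, refine = TRUE) {
  f0 <- radial_sdf(pts, rfun)
  q <- pts
  for (it in 1:6) {
    s <- radial_sdf(q, rfun, grad = TRUE)
    g2 <- rowSums(s$grad^2)
    g2[g2 < 1e-12] <- 1e-12
    q <- q - (s$value / g2) * s$grad
  }
  resid <- abs(radial_sdf(q, rfun))
  # both are distances to actual surface points (along the radial ray and
  # to the projection foot), so the smaller upper bound is the tighter
  # estimate; the ray bound saves the axis region where the projection's
  # gradient is ill-conditioned
  d <- sign(f0) * pmin(abs(f0), sqrt(rowSums((pts - q)^2)) + resid)
  if (refine) {
    # inside groove notches the nearest surface sheet is neither along
    # the ray nor at the projection foot; the few points whose bound is
    # still large get an exhaustive check against a dense surface sample
    idx <- which(abs(d) > 0.1)
    if (length(idx)) {
      u <- unit_sphere_grid(400, 800)
      dense <- u * rfun(u)
      nn <- cpp_nn1(dense, pts[idx, , drop = FALSE])
      d[idx] <- sign(d[idx]) * pmin(abs(d[idx]), nn$dist)
    }
  }
  d
}

#' Distance of points to a phantom surface
#'
#' Signed Euclidean distance to the radial implicit surface, computed by
#' Newton projection; the oracle for noise, quantisation and outlier
#' checks.
#'
#' @param phantom a [make_tooth_phantom()] phantom.
#' @param points n x 3 matrix or [point_cloud()].
#' @param surface `"crown"` or `"pulp"`.
#' @return signed distances in mm (positive outside).
#' @export
surface_distance <- function(phantom, points, surface = c("crown", "pulp")) {
  surface <- match.arg(surface)
  pts <- cloud_points(points)
  p <- phantom$params
  rfun <- if (surface == "crown") {
    function(u) radial_eval(u, p$a, p$b, p$c, p$dirs, p$crown_amp, p$crown_width,
                            groove_phi = p$groove_phi,
                            groove_depth = p$groove_depth)
  } else {
    function(u) radial_eval(u, p$a, p$b, p$c, p$dirs, p$pulp_amp, p$pulp_width, p$pulp_scale)
  }
  radial_distance(pts, rfun)
}

#' Sample a scan-like crown cloud
#'
#' Area-weighted surface samples of the crown above the gingival-margin
#' plane, with Gaussian noise along the surface normal emulating the
#' intraoral scanner (default sigma 0.02 mm, the scanner's 20-micron
#' accuracy class).
#'
#' @param phantom a [make_tooth_phantom()] phantom.
#' @param density_per_mm2 samples per mm^2 of surface.
#' @param noise_sigma_mm normal-direction noise standard deviation.
#' @param seed RNG seed.
#' @return a [point_cloud()] tagged `"scan"`, with face normals.
#' @export
make_scan_cloud <- function(phantom, density_per_mm2 = 50,
                            noise_sigma_mm = 0.02, seed = 1) {
  if (density_per_mm2 <= 0) stop("density must be positive")
  V <- phantom$crown_vertices; F_ <- phantom$crown_faces
  fc <- (V[F_[, 1], ] + V[F_[, 2], ] + V[F_[, 3], ]) / 3
  keep <- fc[, 3] > phantom$margin_z
  F_ <- F_[keep, , drop = FALSE]
  e1 <- V[F_[, 2], ] - V[F_[, 1], ]
  e2 <- V[F_[, 3], ] - V[F_[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(fn^2))
  fn <- fn / area2
  # orient outward (radial surface: outward ~ away from origin)
  fctr <- (V[F_[, 1], ] + V[F_[, 2], ] + V[F_[, 3], ]) / 3
  flip <- rowSums(fn * fctr) < 0
  fn[flip, ] <- -fn[flip, ]
  total_area <- sum(area2) / 2
  n <- max(10, round(density_per_mm2 * total_area))
  with_seed(seed, {
    fi <- sample.int(nrow(F_), n, replace = TRUE, prob = area2)
    r1 <- runif(n); r2 <- runif(n)
    sw <- sqrt(r1)
    b <- cbind(1 - sw, sw * (1 - r2), sw * r2)
    pts <- b[, 1] * V[F_[fi, 1], ] + b[, 2] * V[F_[fi, 2], ] + b[, 3] * V[F_[fi, 3], ]
    nrm <- fn[fi, , drop = FALSE]
    if (noise_sigma_mm > 0) pts <- pts + rnorm(n, 0, noise_sigma_mm) * nrm
    point_cloud(pts, nrm, "scan")
  })
}

#' Generate CBCT-like crown and pulp clouds
#'
#' Emulates the CBCT reconstruction chain: the phantom surfaces are
#' voxelised at `voxel_mm` (default 0.25 mm, the scanner's resolution) and
#' re-extracted by marching tetrahedra, giving quantisation roughness;
#' isotropic Gaussian noise is added; `outlier_frac` of the crown points
#' are replaced by points pushed 1-5 mm off the surface along its normal
#' (the discontinuous/outlying points of real occlusal reconstructions);
#' and `dropout_frac` of the crown points are removed in contiguous
#' occlusal blotches. The pulp cloud shares the frame, so crown and pulp
#' are rigidly consistent by construction.
#'
#' @param phantom a [make_tooth_phantom()] phantom.
#' @param voxel_mm voxel pitch of the emulated CBCT grid.
#' @param noise_sigma_mm isotropic Gaussian noise sd.
#' @param outlier_frac fraction of crown points displaced off-surface.
#' @param dropout_frac fraction of crown points removed in blotches.
#' @param seed RNG seed.
#' @param smooth_iters Laplacian smoothing iterations applied to the
#'   re-extracted isosurface before sampling, as in the CBCT
#'   reconstruction chain being emulated (0 keeps the raw quantised
#'   surface).
#' @return list with `crown` and `pulp` [point_cloud()]s and the
#'   `outlier_indices` into the returned crown cloud.
#' @export
make_cbct_cloud <- function(phantom, voxel_mm = 0.25, noise_sigma_mm = 0.02,
                            outlier_frac = 0.02, dropout_frac = 0.05,
                            seed = 1, smooth_iters = 10) {
  if (outlier_frac < 0 || outlier_frac >= 1 || dropout_frac < 0 || dropout_frac >= 1)
    stop("fractions must lie in [0, 1)")
  p <- phantom$params
  r_crown <- function(u) radial_eval(u, p$a, p$b, p$c, p$dirs, p$crown_amp,
                                     p$crown_width, groove_phi = p$groove_phi,
                                     groove_depth = p$groove_depth)
  r_pulp <- function(u) radial_eval(u, p$a, p$b, p$c, p$dirs, p$pulp_amp, p$pulp_width, p$pulp_scale)
  lim <- p$a * (1 + max(p$crown_amp)) + 2 * voxel_mm
  ax <- seq(-lim, lim, by = voxel_mm)
  az <- seq(-p$c - 2 * voxel_mm, p$c * (1 + max(p$crown_amp)) + 2 * voxel_mm, by = voxel_mm)
  voxelize <- function(rfun) {
    g <- as.matrix(expand.grid(x = ax, y = ax, z = az))
    occ <- radial_sdf(g, rfun) < 0
    arr <- array(as.numeric(occ), c(length(ax), length(ax), length(az)))
    iso <- cpp_march_tets(as.numeric(arr), as.integer(dim(arr)), 0.5)
    V <- iso$vertices
    if (smooth_iters > 0)
      V <- cpp_laplacian_smooth(V, iso$faces, as.integer(smooth_iters), 0.5)
    V <- V * voxel_mm
    V[, 1] <- V[, 1] + ax[1]; V[, 2] <- V[, 2] + ax[1]; V[, 3] <- V[, 3] + az[1]
    list(vertices = V, faces = iso$faces)
  }
  cr <- voxelize(r_crown)
  pu <- voxelize(r_pulp)
  with_seed(seed, {
    crown_pts <- cr$vertices
    pulp_pts <- pu$vertices
    if (noise_sigma_mm > 0) {
      crown_pts <- crown_pts + matrix(rnorm(length(crown_pts), 0, noise_sigma_mm),
                                      ncol = 3)
      pulp_pts <- pulp_pts + matrix(rnorm(length(pulp_pts), 0, noise_sigma_mm),
                                    ncol = 3)
    }
    n <- nrow(crown_pts)
    out_idx <- integer(0)
    n_out <- floor(outlier_frac * n)
    if (n_out > 0) {
      out_idx <- sample.int(n, n_out)
      s <- radial_sdf(crown_pts[out_idx, , drop = FALSE], r_crown, grad = TRUE)
      nrm <- s$grad / sqrt(rowSums(s$grad^2))
      d <- runif(n_out, 1, 5)
      # project to the surface, then push out 1-5 mm along the normal;
      # in concave regions a displaced point can land near another part
      # of the surface, so push such points further until the 1 mm
      # off-surface guarantee holds
      base <- crown_pts[out_idx, , drop = FALSE] -
        (s$value / rowSums(s$grad^2)^0.5) * nrm
      cand <- base + d * nrm
      for (pass in 1:5) {
        off <- abs(radial_distance(cand, r_crown, refine = FALSE))
        bad <- off < 1.05
        if (!any(bad)) break
        d[bad] <- d[bad] + 1
        cand[bad, ] <- base[bad, , drop = FALSE] + d[bad] * nrm[bad, , drop = FALSE]
      }
      crown_pts[out_idx, ] <- cand
    }
    n_drop <- floor(dropout_frac * n)
    keep <- rep(TRUE, n)
    if (n_drop > 0) {
      n_blotch <- max(1, min(3, n_drop))
      occl <- which(crown_pts[, 3] > stats::median(crown_pts[, 3]) & keep)
      seeds <- sample(occl, n_blotch)
      per <- ceiling(n_drop / n_blotch)
      for (sdx in seeds) {
        kk <- min(per, n)
        nb <- cpp_knn(crown_pts, crown_pts[sdx, , drop = FALSE], as.integer(kk))
        keep[as.integer(nb)] <- FALSE
      }
      # outliers are never dropped, so the displaced count stays exact
      keep[out_idx] <- TRUE
    }
    crown_keep <- which(keep)
    crown <- point_cloud(crown_pts[crown_keep, , drop = FALSE],
                         source_tag = "cbct_crown")
    pulp <- point_cloud(pulp_pts, source_tag = "cbct_pulp")
    list(crown = crown, pulp = pulp,
         outlier_indices = match(out_idx, crown_keep))
  })
}

#' Perturbation presets for initial pose deviations
#'
#' @param name `"small"` (<= 5 degrees, <= 1 mm) or `"large"`
#'   (<= 25 degrees, <= 5 mm).
#' @return list with `name`, `rotation_range_deg`, `translation_range_mm`.
#' @export
perturbation_preset <- function(name = c("small", "large")) {
  name <- match.arg(name)
  if (name == "small") list(name = "small", rotation_range_deg = 5,
                            translation_range_mm = 1)
  else list(name = "large", rotation_range_deg = 25, translation_range_mm = 5)
}

#' Apply a random rigid perturbation to a cloud
#'
#' Random rotation axis and angle (uniform up to the range) about the
#' cloud centroid, plus a random translation; returns the moved cloud and
#' the exact transform so recovery can be scored against ground truth.
#'
#' @param cloud a [point_cloud()].
#' @param preset a preset name / [perturbation_preset()] list, or `NULL`
#'   when giving explicit ranges.
#' @param angle_deg,trans_mm explicit ranges (used when `preset` is NULL).
#' @param seed RNG seed.
#' @return list with `cloud` (moved) and `transform` (the applied
#'   [rigid_transform()], so `apply_transform(original, transform)`
#'   reproduces the moved cloud).
#' @export
perturb_pose <- function(cloud, preset = "small", angle_deg = NULL,
                         trans_mm = NULL, seed = 1) {
  if (!is.null(preset)) {
    if (is.character(preset)) preset <- perturbation_preset(preset)
    angle_deg <- preset$rotation_range_deg
    trans_mm <- preset$translation_range_mm
  }
  if (angle_deg < 0 || trans_mm < 0) stop("ranges must be >= 0")
  ctr <- colMeans(cloud$points)
  with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, angle_deg)
    td <- rnorm(3); td <- td / sqrt(sum(td^2))
    tmag <- runif(1, 0, trans_mm)
    R <- if (ang > 0) rotation_about_axis(ax, ang) else diag(3)
    tvec <- ctr - as.numeric(R %*% ctr) + tmag * td
    tf <- rigid_transform(R, tvec)
    list(cloud = apply_transform(cloud, tf), transform = tf)
  })
}

#' Segmentation phantom volume
#'
#' A capped-cylinder "tooth" (cylinder plus hemispherical occlusal cap)
#' containing a smaller coaxial capped-cylinder "pulp" cavity, rendered at
#' the given class intensities with optional Gaussian noise, together with
#' the ground-truth label volume.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel pitch (mm).
#' @param intensities named vector with `background`, `pulp`, `tooth`
#'   intensity levels (the defaults step by 50).
#' @param noise_sigma Gaussian noise sd.
#' @param seed RNG seed.
#' @param tooth_radius_mm,pulp_radius_mm,tooth_height_mm solid dimensions.
#' @return list with `volume` ([volume_image()]) and `truth`
#'   ([label_volume()] with legend background/tooth/pulp).
#' @export
make_segmentation_phantom_volume <- function(shape = c(48, 48, 40),
                                             spacing = 0.25,
                                             intensities = c(background = 50,
                                                             pulp = 100,
                                                             tooth = 150),
                                             noise_sigma = 0, seed = 1,
                                             tooth_radius_mm = 3.5,
                                             pulp_radius_mm = 1.6,
                                             tooth_height_mm = 5) {
  if (length(intensities) < 2) stop("need at least 2 intensity classes")
  ctr <- (shape / 2) * spacing
  xs <- (seq_len(shape[1]) - 0.5) * spacing
  ys <- (seq_len(shape[2]) - 0.5) * spacing
  zs <- (seq_len(shape[3]) - 0.5) * spacing
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  rho2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2
  # centre the full solid (cylinder plus occlusal cap) in the grid
  zb <- ctr[3] - (tooth_height_mm + tooth_radius_mm) / 2
  zt <- zb + tooth_height_mm
  capped <- function(R) {
    cyl <- rho2 <= R^2 & g[, 3] >= zb & g[, 3] <= zt
    cap <- rho2 + (g[, 3] - zt)^2 <= R^2 & g[, 3] > zt
    cyl | cap
  }
  tooth_solid <- capped(tooth_radius_mm)
  pulp_solid <- capped(pulp_radius_mm) & g[, 3] >= zb + 2 * spacing
  labels <- array(0L, shape)
  labels[array(tooth_solid, shape)] <- 2L
  labels[array(pulp_solid, shape)] <- 3L
  vox <- array(intensities[["background"]], shape)
  vox[labels == 2L] <- intensities[["tooth"]]
  vox[labels == 3L] <- intensities[["pulp"]]
  if (noise_sigma > 0) {
    with_seed(seed, {
      vox <- vox + array(rnorm(length(vox), 0, noise_sigma), shape)
    })
  }
  list(volume = volume_image(vox, spacing),
       truth = label_volume(labels, c(background = 0L, tooth = 2L, pulp = 3L),
                            spacing))
}
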