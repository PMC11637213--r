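# CBCT volume preprocessing: hybrid wavelet + NL-means filtering, adaptive
# spiking-cortical-model (SCM) segmentation, and isosurface extraction of
# labelled structures into point clouds.

#' Construct a volume image
#'
#' A 3-D scalar intensity grid with isotropic or per-axis voxel spacing in
#' mm, the input to filtering and segmentation.
#'
#' @param voxels 3-D numeric array of intensities.
#' @param spacing voxel spacing in mm; a scalar or length-3 vector.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = 0.25) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) stop("voxels must be a 3-D array")
  if (!all(is.finite(voxels))) stop("intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(voxels = voxels, spacing = spacing), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels at (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Construct a label volume
#'
#' @param labels 3-D integer array of non-negative labels.
#' @param legend named integer vector mapping class names (`background`,
#'   `alveolar`, `tooth`, `pulp`, ...) to label values; must cover every
#'   label present.
#' @param spacing voxel spacing (mm).
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, legend, spacing = 0.25) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  present <- sort(unique(as.integer(labels)))
  if (!all(present %in% legend))
    stop("legend must cover every label present in the volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  structure(list(labels = labels, legend = legend, spacing = spacing),
            class = "label_volume")
}

# ---------------------------------------------------------------------------
# Hybrid filtering: per-slice Haar wavelet soft shrinkage + NL-means
# ---------------------------------------------------------------------------

# one 2-D Haar analysis step with replicate padding to even dims
haar_step <- function(m) {
  pr <- nrow(m) %% 2; pc <- ncol(m) %% 2
  if (pr) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (pc) m <- cbind(m, m[, ncol(m), drop = FALSE])
  o <- seq(1, nrow(m), 2); e <- o + 1
  lo_r <- (m[o, , drop = FALSE] + m[e, , drop = FALSE]) / sqrt(2)
  hi_r <- (m[o, , drop = FALSE] - m[e, , drop = FALSE]) / sqrt(2)
  oc <- seq(1, ncol(m), 2); ec <- oc + 1
  list(LL = (lo_r[, oc, drop = FALSE] + lo_r[, ec, drop = FALSE]) / sqrt(2),
       LH = (lo_r[, oc, drop = FALSE] - lo_r[, ec, drop = FALSE]) / sqrt(2),
       HL = (hi_r[, oc, drop = FALSE] + hi_r[, ec, drop = FALSE]) / sqrt(2),
       HH = (hi_r[, oc, drop = FALSE] - hi_r[, ec, drop = FALSE]) / sqrt(2),
       pad = c(pr, pc))
}

haar_unstep <- function(b, out_dim) {
  lo_r <- matrix(0, nrow(b$LL), 2 * ncol(b$LL))
  hi_r <- matrix(0, nrow(b$LL), 2 * ncol(b$LL))
  oc <- seq(1, ncol(lo_r), 2); ec <- oc + 1
  lo_r[, oc] <- (b$LL + b$LH) / sqrt(2)
  lo_r[, ec] <- (b$LL - b$LH) / sqrt(2)
  hi_r[, oc] <- (b$HL + b$HH) / sqrt(2)
  hi_r[, ec] <- (b$HL - b$HH) / sqrt(2)
  m <- matrix(0, 2 * nrow(b$LL), ncol(lo_r))
  o <- seq(1, nrow(m), 2); e <- o + 1
  m[o, ] <- (lo_r + hi_r) / sqrt(2)
  m[e, ] <- (lo_r - hi_r) / sqrt(2)
  m[seq_len(out_dim[1]), seq_len(out_dim[2]), drop = FALSE]
}

soft_thresh <- function(x, lam) sign(x) * pmax(abs(x) - lam, 0)

# multi-level Haar soft shrinkage with the universal threshold
haar_denoise_slice <- function(m, levels) {
  dims <- list(); bands <- list(); cur <- m
  for (l in seq_len(levels)) {
    dims[[l]] <- dim(cur)
    bands[[l]] <- haar_step(cur)
    cur <- bands[[l]]$LL
  }
  sigma <- mad(as.numeric(bands[[1]]$HH), center = 0)
  lam <- sigma * sqrt(2 * log(length(m)))
  if (lam > 0) {
    for (l in seq_len(levels)) {
      bands[[l]]$LH <- soft_thresh(bands[[l]]$LH, lam)
      bands[[l]]$HL <- soft_thresh(bands[[l]]$HL, lam)
      bands[[l]]$HH <- soft_thresh(bands[[l]]$HH, lam)
    }
  }
  for (l in rev(seq_len(levels))) {
    bands[[l]]$LL <- cur
    cur <- haar_unstep(bands[[l]], dims[[l]])
  }
  cur
}

#' Hybrid wavelet + NL-means volume filter
#'
#' Slice-wise denoising that sharpens pulp and enamel contours before
#' segmentation: a multi-level Haar wavelet soft shrinkage (universal
#' threshold estimated from the finest diagonal band) followed by
#' non-local-means averaging. `block` is the patch radius, `window` the
#' full (odd) width of the search window, and `decay` the Gaussian
#' bandwidth on the intensity scale; the defaults are block 2, window 5,
#' decay 10. Output intensities are clamped to the input range.
#'
#' @param vol a [volume_image()].
#' @param block patch radius (>= 1).
#' @param window full width of the NL-means search window (odd, > block).
#' @param decay NL-means bandwidth (> 0).
#' @param wavelet_levels Haar decomposition depth.
#' @return the filtered [volume_image()].
#' @export
hybrid_filter <- function(vol, block = 2, window = 5, decay = 10,
                          wavelet_levels = 2) {
  stopifnot(inherits(vol, "volume_image"))
  if (block < 1) stop("block must be >= 1")
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= block) stop("window must exceed block")
  if (decay <= 0) stop("decay must be positive")
  d <- dim(vol$voxels)
  if (min(d[1], d[2]) < window)
    stop("volume slices are thinner than the search window")
  lo <- min(vol$voxels); hi <- max(vol$voxels)
  out <- vol$voxels
  for (k in seq_len(d[3])) {
    sl <- haar_denoise_slice(vol$voxels[, , k], wavelet_levels)
    sl <- cpp_nlmeans(sl, as.integer(block), as.integer(window), decay)
    out[, , k] <- sl
  }
  out[out < lo] <- lo
  out[out > hi] <- hi
  volume_image(out, vol$spacing)
}

# ---------------------------------------------------------------------------
# Adaptive SCM segmentation
# ---------------------------------------------------------------------------

#' Adaptive SCM parameters for one slice
#'
#' Derives the spiking-cortical-model constants from the slice statistics:
#' threshold decay `alpha_e = C / mu`, threshold magnitude `V_E = 2 mu`,
#' coupling strength `beta = a * ln(mu)`, internal-activity decay
#' `alpha_u = log(1 / var(I))` (natural log), and initial threshold
#' `E0 = max(I)`, where `mu` is the slice mean intensity. `C` and `a` are
#' the model's experimental constants; see [run_config()] for the package
#' defaults and the vignette for their rationale.
#'
#' @param slice 2-D numeric intensity matrix with positive mean and
#'   non-zero variance.
#' @param C threshold-decay constant of the `alpha_e` rule.
#' @param a coupling constant of the `beta` rule.
#' @param W coupling kernel (square, odd side; default 3x3 inverse-distance
#'   weights with zero centre).
#' @param V_L coupling amplification (default 1).
#' @param n_iter iteration count (default 40).
#' @return an object of class `scm_params`.
#' @export
scm_adaptive_params <- function(slice, C, a, W = NULL, V_L = 1, n_iter = 40) {
  slice <- as.matrix(slice)
  if (!length(slice)) stop("slice must be non-empty")
  mu <- mean(slice)
  v <- var(as.numeric(slice))
  if (mu <= 0) stop("slice mean intensity must be positive")
  if (v == 0) stop("degenerate image: zero variance (alpha_u undefined)")
  if (is.null(W)) {
    W <- matrix(c(1 / sqrt(2), 1, 1 / sqrt(2),
                  1, 0, 1,
                  1 / sqrt(2), 1, 1 / sqrt(2)), 3, 3)
  }
  structure(list(alpha_e = C / mu,
                 V_E = 2 * mu,
                 beta = a * log(mu),
                 alpha_u = log(1 / v),
                 E0 = max(slice),
                 C = C, a = a, W = W, V_L = V_L,
                 n_iter = as.integer(n_iter)),
            class = "scm_params")
}

# 3x3 (or general odd) kernel convolution of a binary/real matrix with
# zero padding, via shift-and-add
conv_kernel <- function(m, W) {
  kr <- (nrow(W) - 1) / 2
  kc <- (ncol(W) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (di in -kr:kr) {
    for (dj in -kc:kc) {
      w <- W[di + kr + 1, dj + kc + 1]
      if (w == 0) next
      src_r <- max(1, 1 - di):min(nrow(m), nrow(m) - di)
      src_c <- max(1, 1 - dj):min(ncol(m), ncol(m) - dj)
      out[src_r, src_c] <- out[src_r, src_c] +
        w * m[src_r + di, src_c + dj]
    }
  }
  out
}

#' SCM segmentation of one slice
#'
#' Runs the spiking-cortical-model recurrence
#' `U(n) = exp(-alpha_u) U(n-1) + S (1 + beta V_L (W * Y(n-1)))`,
#' `Y(n) = 1` where `U(n) > E(n-1)`,
#' `E(n) = exp(-alpha_e) E(n-1) + V_E Y(n)`
#' for `n_iter` steps and labels each pixel by the synchronised pulse it
#' first fires in. Because noise lets a pulse spill into the adjacent
#' iteration, first-firing iterations separated by a gap of at most one
#' step are merged into one label; distinct intensity classes land several
#' iterations apart under the adaptive parameter rules and are unaffected.
#' Pixels that never fire are labelled 0 (background); if more than half
#' the slice never fires a warning is raised.
#'
#' @param slice 2-D numeric intensity matrix.
#' @param params an [scm_adaptive_params()] object.
#' @return list with `labels` (integer matrix, 0 = never fired) and
#'   `firing` (first-firing iteration, NA where never fired).
#' @export
scm_segment_slice <- function(slice, params) {
  stopifnot(inherits(params, "scm_params"))
  S <- as.matrix(slice)
  U <- matrix(0, nrow(S), ncol(S))
  E <- matrix(params$E0, nrow(S), ncol(S))
  Y <- matrix(0, nrow(S), ncol(S))
  firing <- matrix(NA_integer_, nrow(S), ncol(S))
  fu <- exp(-params$alpha_u)
  fe <- exp(-params$alpha_e)
  for (n in seq_len(params$n_iter)) {
    L <- conv_kernel(Y, params$W)
    U <- fu * U + S * (1 + params$beta * params$V_L * L)
    Y <- (U > E) * 1
    E <- fe * E + params$V_E * Y
    newly <- is.na(firing) & Y > 0
    firing[newly] <- n
  }
  if (mean(is.na(firing)) > 0.5)
    warning("more than half the pixels never fired; labelled background")
  labels <- merge_firing_bins(firing)
  list(labels = labels, firing = firing)
}

# group first-firing iterations into synchronised pulses: heavy bins
# (holding at least 0.2% of the pixels) separated by a gap <= 1 iteration
# form one pulse; sparse straggler bins — boundary pixels with
# intermediate intensities — join the nearest heavy pulse but cannot
# bridge two of them. Earlier (brighter) pulses get lower labels.
merge_firing_bins <- function(firing) {
  labels <- matrix(0L, nrow(firing), ncol(firing))
  tab <- table(firing[!is.na(firing)])
  if (!length(tab)) return(labels)
  iters <- as.integer(names(tab))
  heavy <- tab >= max(5, 0.002 * sum(!is.na(firing)))
  if (!any(heavy)) heavy[] <- TRUE
  hi <- iters[heavy]
  grp_h <- cumsum(c(1, diff(hi) > 2))
  grp <- integer(length(iters))
  grp[match(hi, iters)] <- grp_h
  light <- which(!heavy)
  for (j in light) grp[j] <- grp_h[which.min(abs(hi - iters[j]))]
  map <- stats::setNames(grp, iters)
  idx <- !is.na(firing)
  labels[idx] <- as.integer(map[as.character(firing[idx])])
  labels
}

#' Segment tooth and pulp from a CBCT volume
#'
#' Slice-wise adaptive SCM segmentation followed by a 3-D merge: each
#' slice is unit-normalised, parameters come from the adaptive rules, the
#' brightest SCM pulse groups form a candidate hard-tissue mask, 3-D
#' connected components of that mask rank by mean intensity to give the
#' tooth label(s), and the pulp is recovered as the low-intensity cavity
#' morphologically enclosed by tooth (interior voxels unreachable from the
#' volume border through non-tooth space). Mid-intensity voxels outside
#' the tooth are labelled alveolar.
#'
#' @param vol a filtered [volume_image()].
#' @param C,a adaptive SCM constants (defaults from [run_config()]:
#'   `C = 0.01 * max`, `a = -0.02` on unit-normalised slices).
#' @param n_iter SCM iterations per slice.
#' @param min_component_voxels components smaller than this are dropped.
#' @param bright_threshold hard-tissue gate on the globally unit-normalised
#'   intensity scale: pulse groups below it never enter the tooth mask.
#' @return a [label_volume()] with legend
#'   `c(background = 0, alveolar = 1, tooth = 2, pulp = 3)`; the pulp label
#'   is absent (with a warning) when no enclosed cavity exists.
#' @export
segment_tooth_and_pulp <- function(vol, C = NULL, a = -0.02, n_iter = 40,
                                   min_component_voxels = 30,
                                   bright_threshold = 0.45) {
  stopifnot(inherits(vol, "volume_image"))
  v <- vol$voxels
  d <- dim(v)
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("volume has no intensity structure; returning empty labels")
    return(label_volume(array(0L, d),
                        c(background = 0L, alveolar = 1L, tooth = 2L),
                        vol$spacing))
  }
  vn <- (v - rng[1]) / diff(rng)  # unit-normalised for stable SCM dynamics
  if (is.null(C)) C <- 0.01 * max(vn)
  bright <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- vn[, , k]
    if (var(as.numeric(sl)) == 0 || mean(sl) <= 0) next
    p <- scm_adaptive_params(sl, C = C, a = a, n_iter = n_iter)
    seg <- suppressWarnings(scm_segment_slice(sl, p))
    if (!any(seg$labels > 0)) next
    # brightest pulse groups: keep groups whose mean intensity is at least
    # 70% of the brightest group's mean (enamel + dentin band) and bright
    # on the global scale, so slices without hard tissue contribute
    # nothing
    gm <- tapply(sl[seg$labels > 0], seg$labels[seg$labels > 0], mean)
    keep <- as.integer(names(gm)[gm >= 0.7 * max(gm) & gm >= bright_threshold])
    bright[, , k] <- seg$labels %in% keep
  }
  lab <- cpp_label_components(as.logical(bright), as.integer(d))
  lab <- array(lab, d)
  if (!any(lab > 0)) {
    warning("no tooth component found")
    return(label_volume(array(0L, d),
                        c(background = 0L, alveolar = 1L, tooth = 2L),
                        vol$spacing))
  }
  sizes <- table(lab[lab > 0])
  comp_mean <- tapply(vn[lab > 0], lab[lab > 0], mean)
  ok <- names(sizes)[sizes >= min_component_voxels]
  if (!length(ok)) ok <- names(sizes)[which.max(sizes)]
  comp_mean <- comp_mean[ok]
  tooth_ids <- as.integer(names(comp_mean)[comp_mean >= 0.8 * max(comp_mean)])
  tooth <- array(lab %in% tooth_ids, d)
  # pulp: cavity enclosed by tooth
  outside <- array(cpp_outside_fill(as.logical(tooth), as.integer(d)), d)
  pulp <- !tooth & !outside
  # boundary refinement: the filter blurs the cavity wall, so the voxel
  # shell around the cavity lands in the tooth pulse; reassign tooth
  # voxels adjacent to the cavity whose intensity is nearer the cavity
  # mean than the tooth mean
  if (any(pulp)) {
    for (pass in 1:3) {
      mp <- mean(vn[pulp]); mt <- mean(vn[tooth])
      shell <- dilate6(pulp, d) & tooth
      move <- shell & abs(vn - mp) < abs(vn - mt)
      if (!any(move)) break
      pulp <- pulp | move
      tooth <- tooth & !move
    }
  }
  out <- array(0L, d)
  # alveolar: mid-intensity voxels outside the tooth
  alveolar <- outside & vn > 0.35 & !tooth
  out[alveolar] <- 1L
  out[tooth] <- 2L
  legend <- c(background = 0L, alveolar = 1L, tooth = 2L)
  if (any(pulp)) {
    out[pulp] <- 3L
    legend <- c(legend, pulp = 3L)
  } else {
    warning("no pulp-candidate cavity found; pulp label absent")
  }
  lv <- label_volume(out, legend, vol$spacing)
  attr(lv, "n_tooth_components") <- length(tooth_ids)
  lv
}

# one 6-connected dilation step of a logical 3-D array
dilate6 <- function(m, d) {
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Extract a labelled structure's surface as a point cloud
#'
#' Marching-tetrahedra isosurface of the binary mask of `which` at level
#' 0.5, optionally Laplacian-smoothed, scaled into mm by the voxel
#' spacing. Vertex normals are averaged from incident face normals and
#' oriented away from the structure centroid.
#'
#' @param labels a [label_volume()].
#' @param which label value or legend name to extract.
#' @param smoothing_iters Laplacian smoothing iterations (0 = raw
#'   isosurface vertices).
#' @return a [point_cloud()] with normals; the triangulation is attached
#'   as attributes `faces` and `vertices_raw`.
#' @export
extract_surface_cloud <- function(labels, which, smoothing_iters = 5) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.character(which)) {
    if (!which %in% names(labels$legend)) stop("label name not in legend")
    which <- labels$legend[[which]]
  }
  mask <- labels$labels == which
  if (!any(mask)) stop("label absent from volume")
  d <- dim(labels$labels)
  iso <- cpp_march_tets(as.numeric(mask), as.integer(d), 0.5)
  if (!nrow(iso$vertices)) stop("empty surface for this label")
  V <- iso$vertices
  raw <- sweep(V, 2, labels$spacing, "*")
  if (smoothing_iters > 0)
    V <- cpp_laplacian_smooth(V, iso$faces, as.integer(smoothing_iters), 0.5)
  V <- sweep(V, 2, labels$spacing, "*")
  nrm <- vertex_normals(V, iso$faces)
  cl <- point_cloud(V, nrm, "other")
  attr(cl, "faces") <- iso$faces
  attr(cl, "vertices_raw") <- raw
  cl
}

# area-weighted vertex normals from faces, oriented away from the centroid
vertex_normals <- function(V, F) {
  n <- matrix(0, nrow(V), 3)
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ctr <- colMeans(V)
  fc <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  flip <- rowSums(fn * sweep(fc, 2, ctr)) < 0
  fn[flip, ] <- -fn[flip, ]
  for (j in 1:3) {
    for (c in 1:3) {
      acc <- tapply(fn[, c], F[, j], sum)
      n[as.integer(names(acc)), c] <- n[as.integer(names(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  # re-orient any stragglers away from the centroid
  flip <- rowSums(n * sweep(V, 2, ctr)) < 0
  n[flip, ] <- -n[flip, ]
  n
}

#' Dice coefficient between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return the Dice overlap `2|a & b| / (|a| + |b|)`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
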