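# Shared geometric primitives: point clouds, rigid transforms, kNN,
# PCA normals/frames, oriented bounding boxes. All coordinates are in mm;
# all angles reported by the package are in degrees.

#' Construct a point cloud
#'
#' A point cloud is the universal currency of every registration stage:
#' an ordered set of 3-D points in millimetres with optional per-point unit
#' normals and a tag recording which imaging source it came from.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), or anything
#'   coercible to one.
#' @param normals optional numeric matrix of unit normals, same number of
#'   rows as `points`.
#' @param source_tag one of `"scan"`, `"cbct_crown"`, `"cbct_pulp"`,
#'   `"other"`.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL,
                        source_tag = c("other", "scan", "cbct_crown", "cbct_pulp")) {
  source_tag <- match.arg(source_tag)
  points <- as_xyz_matrix(points, "points")
  if (!all(is.finite(points))) stop("point coordinates must all be finite")
  if (!is.null(normals)) {
    normals <- as_xyz_matrix(normals, "normals")
    if (nrow(normals) != nrow(points))
      stop("normals must have one row per point")
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6))
      stop("normals must be unit length (within 1e-6)")
  }
  structure(list(points = points, normals = normals, source_tag = source_tag),
            class = "point_cloud")
}

as_xyz_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points [%s]%s\n", nrow(x$points), x$source_tag,
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Construct a rigid transform
#'
#' A proper rigid motion: rotation (3x3, orthogonal, det +1) plus a
#' translation in mm. Transforms compose and invert; they are the output of
#' every registration routine.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    stop("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper orthogonal (R'R = I, det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(T2, T1)` is the transform that applies `T1` first and
#' then `T2`.
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(project_so3(t2$rotation %*% t1$rotation),
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

# nearest proper rotation (polar projection via SVD)
project_so3 <- function(R) {
  s <- svd(R)
  d <- diag(c(1, 1, det(s$u %*% t(s$v))))
  s$u %*% d %*% t(s$v)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return rotation angle in degrees.
#' @export
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Axis-angle rotation matrix
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to a point cloud
#'
#' Points map as `R p + t`; normals (when present) rotate as `R n`.
#'
#' @param cloud a [point_cloud()].
#' @param tf a [rigid_transform()].
#' @return the transformed [point_cloud()].
#' @export
apply_transform <- function(cloud, tf) {
  pts <- cloud$points %*% t(tf$rotation)
  pts <- sweep(pts, 2, tf$translation, "+")
  nrm <- if (is.null(cloud$normals)) NULL else cloud$normals %*% t(tf$rotation)
  point_cloud(pts, nrm, cloud$source_tag)
}

#' k-nearest-neighbour search
#'
#' Indices of the `k` target points nearest to `query` by Euclidean
#' distance, in ascending distance order. Equidistant ties resolve to the
#' lower index, for determinism across platforms.
#'
#' @param target a [point_cloud()] or 3-column matrix.
#' @param query a length-3 point or an m x 3 matrix of query points.
#' @param k neighbour count (`k <= n_points(target)`).
#' @return integer vector of indices (or an m x k matrix for matrix input).
#' @export
knn_search <- function(target, query, k) {
  pts <- cloud_points(target)
  if (k > nrow(pts)) stop("k exceeds the number of target points")
  if (k < 1) stop("k must be >= 1")
  qm <- if (is.matrix(query)) query else matrix(query, 1, 3)
  idx <- cpp_knn(pts, as_xyz_matrix(qm, "query"), as.integer(k))
  if (is.matrix(query)) idx else as.integer(idx[1, ])
}

cloud_points <- function(x) {
  if (inherits(x, "point_cloud")) x$points else as_xyz_matrix(x, "cloud")
}

#' Estimate per-point surface normals
#'
#' Each normal is the smallest-eigenvalue eigenvector of the covariance of
#' the point and its `k` nearest neighbours, normalised to unit length and
#' oriented away from the cloud centroid (crown surfaces are locally convex
#' occlusally, so this yields a consistent outward hemisphere). Set
#' `flip = TRUE` to orient toward the centroid instead.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbour count (`k >= 3`, cloud must have at least `k + 1`
#'   points).
#' @param flip flip all normals toward the centroid.
#' @return the cloud with `normals` filled.
#' @export
estimate_normals <- function(cloud, k = 10, flip = FALSE) {
  if (k < 3) stop("k must be >= 3")
  if (n_points(cloud) < k + 1) stop("cloud must have at least k + 1 points")
  res <- cpp_estimate_normals(cloud$points, as.integer(k))
  if (length(res$degenerate))
    stop(sprintf("degenerate neighbourhood (coincident points) at indices: %s",
                 paste(res$degenerate, collapse = ", ")))
  nrm <- res$normals
  if (flip) nrm <- -nrm
  point_cloud(cloud$points, nrm, cloud$source_tag)
}

#' PCA frame of a point cloud
#'
#' Origin at the centroid; axes are covariance eigenvectors in descending
#' variance order. The first two axes' signs are canonicalised so their dot
#' product with the corresponding global axis is non-negative; the third is
#' their cross product, giving a right-handed triad. These frames anchor
#' the crown-pulp pose-deviation metrics.
#'
#' @param cloud a [point_cloud()].
#' @return an object of class `pca_frame` with fields `origin` and `axes`
#'   (3x3 matrix, axes in rows).
#' @export
pca_frame <- function(cloud) {
  pts <- cloud_points(cloud)
  if (nrow(pts) < 4) stop("need at least 4 points for a PCA frame")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  C <- crossprod(cc) / nrow(cc)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] < 1e-12 * max(e$values[1], 1e-300) || e$values[1] <= 0)
    stop("degenerate frame: points are collinear or coincident")
  a1 <- e$vectors[, 1]
  a2 <- e$vectors[, 2]
  if (a1[1] < 0 || (a1[1] == 0 && sum(a1) < 0)) a1 <- -a1
  if (a2[2] < 0 || (a2[2] == 0 && sum(a2) < 0)) a2 <- -a2
  a3 <- cross3(a1, a2)
  structure(list(origin = ctr, axes = rbind(a1, a2, a3, deparse.level = 0)),
            class = "pca_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Oriented bounding box of a point cloud
#'
#' The box centre is the arithmetic mean of the points; axes come from the
#' covariance PCA with the same sign canonicalisation as [pca_frame()], and
#' half-extents are the maximal absolute projections of the centred points
#' on each axis, so the box contains every point. Corners are labelled
#' A, B, C, D on the face toward the third axis and A', B', C', D' on the
#' opposite (base) face.
#'
#' @param cloud a [point_cloud()].
#' @return an object of class `oriented_bbox` with fields `center`, `axes`
#'   (rows), `half_extents`, `corners` (named 8x3 matrix).
#' @export
compute_obb <- function(cloud) {
  pts <- cloud_points(cloud)
  if (nrow(pts) < 4) stop("need at least 4 points")
  fr <- tryCatch(pca_frame(pts), error = function(e)
    stop("degenerate extent: points are collinear or coincident"))
  ctr <- colMeans(pts)
  proj <- sweep(pts, 2, ctr) %*% t(fr$axes)
  he <- apply(abs(proj), 2, max)
  if (he[3] < 1e-9 * max(he[1], 1))
    stop("degenerate extent: points are coplanar")
  corners <- obb_corners(ctr, fr$axes, he)
  structure(list(center = ctr, axes = fr$axes, half_extents = he,
                 corners = corners),
            class = "oriented_bbox")
}

obb_corners <- function(center, axes, he) {
  sgn <- rbind(c( 1,  1,  1),   # A
               c(-1,  1,  1),   # B
               c(-1, -1,  1),   # C
               c( 1, -1,  1),   # D
               c( 1,  1, -1),   # A'
               c(-1,  1, -1),   # B'
               c(-1, -1, -1),   # C'
               c( 1, -1, -1))   # D'
  out <- t(apply(sgn, 1, function(s) center + as.numeric(t(axes) %*% (s * he))))
  rownames(out) <- c("A", "B", "C", "D", "A'", "B'", "C'", "D'")
  out
}

#' @export
print.oriented_bbox <- function(x, ...) {
  cat(sprintf("<oriented_bbox> center (%.3f, %.3f, %.3f), half-extents (%.3f, %.3f, %.3f) mm\n",
              x$center[1], x$center[2], x$center[3],
              x$half_extents[1], x$half_extents[2], x$half_extents[3]))
  invisible(x)
}

#' Deterministically downsample a point cloud
#'
#' Keeps `n` points at evenly spaced index strides (no randomness), for
#' bounding the cost of registration runs.
#'
#' @param cloud a [point_cloud()].
#' @param n target point count; clouds smaller than `n` pass through.
#' @return the downsampled [point_cloud()].
#' @export
downsample_cloud <- function(cloud, n) {
  m <- n_points(cloud)
  if (m <= n) return(cloud)
  keep <- unique(round(seq(1, m, length.out = n)))
  point_cloud(cloud$points[keep, , drop = FALSE],
              if (is.null(cloud$normals)) NULL else cloud$normals[keep, , drop = FALSE],
              cloud$source_tag)
}
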