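# Equivalent-crown construction: align the scan crown's oriented bounding
# box with the CBCT crown's, then cut the CBCT tooth at the scan box's
# base plane so both clouds cover comparable anatomy.

#' Align the scan OBB onto the CBCT OBB
#'
#' Returns the rigid transform that rotates the scan box axes parallel to
#' the CBCT box axes (prong A-D to A-D, A-B to A-B) and moves the scan
#' centre to the mixed coordinate `(x_ct, y_ct, z_op)`: x and y are taken
#' from the CBCT box, the height coordinate keeps the scan's own value.
#' Axis sign ambiguities (180-degree flips) resolve to the minimal
#' rotation, with a warning when a prong pair is near-antiparallel.
#'
#' @param scan_obb,cbct_obb [compute_obb()] boxes.
#' @return the aligning [rigid_transform()] (to be applied to the scan).
#' @export
align_obb_centers <- function(scan_obb, cbct_obb) {
  A_op <- scan_obb$axes   # rows
  A_ct <- cbct_obb$axes
  # match axes by sign so each scan axis pairs with the same-index CBCT
  # axis with positive dot product (minimal rotation)
  d <- diag(A_ct %*% t(A_op))
  if (any(d < -0.999))
    warning("near-antiparallel OBB prongs; resolved by minimal rotation")
  s <- ifelse(d < 0, -1, 1)
  if (prod(s) < 0) {
    # keep det(+1): flip the axis with the smallest |dot| back
    j <- which.min(abs(d))
    s[j] <- -s[j]
    warning("axis sign ambiguity resolved to keep a proper rotation")
  }
  A_op_s <- A_op * s
  R <- project_so3(t(A_ct) %*% A_op_s)
  target <- c(cbct_obb$center[1], cbct_obb$center[2], scan_obb$center[3])
  tr <- target - as.numeric(R %*% scan_obb$center)
  rigid_transform(R, tr)
}

#' Base plane of an oriented bounding box
#'
#' The face A'B'C'D' opposite the occlusal side: the plane through
#' `center - h3 * axis3` whose normal (the third box axis) points toward
#' the box centre, i.e. occlusally.
#'
#' @param obb a [compute_obb()] box.
#' @return list with `point` and unit `normal`.
#' @export
obb_base_plane <- function(obb) {
  n <- obb$axes[3, ]
  p <- obb$center - obb$half_extents[3] * n
  list(point = p, normal = n)
}

#' Crop the CBCT tooth at the scan OBB base plane
#'
#' Keeps the CBCT points on the occlusal side of the aligned scan box's
#' bottom face (signed distance >= 0), producing the equivalent crown
#' cloud that matches the scanned crown's extent.
#'
#' @param cbct_tooth a [point_cloud()] of the full CBCT tooth.
#' @param scan_obb_after_alignment the scan [compute_obb()] box already
#'   moved by [align_obb_centers()].
#' @return list of class `equivalence_result` with `cut_plane`,
#'   `cropped_cbct_crown`, and the retained `indices`.
#' @export
crop_crown_by_obb_base <- function(cbct_tooth, scan_obb_after_alignment) {
  if (!n_points(cbct_tooth)) stop("CBCT tooth cloud is empty")
  pl <- obb_base_plane(scan_obb_after_alignment)
  sd <- as.numeric(sweep(cbct_tooth$points, 2, pl$point) %*% pl$normal)
  keep <- which(sd >= 0)
  if (!length(keep))
    stop("no CBCT points on the occlusal side of the cut plane (misalignment?)")
  cropped <- point_cloud(cbct_tooth$points[keep, , drop = FALSE],
                         if (is.null(cbct_tooth$normals)) NULL
                         else cbct_tooth$normals[keep, , drop = FALSE],
                         "cbct_crown")
  structure(list(cut_plane = pl, cropped_cbct_crown = cropped, indices = keep),
            class = "equivalence_result")
}

#' Transform an oriented bounding box
#'
#' @param obb a [compute_obb()] box.
#' @param tf a [rigid_transform()].
#' @return the moved box.
#' @export
transform_obb <- function(obb, tf) {
  center <- as.numeric(tf$rotation %*% obb$center) + tf$translation
  axes <- obb$axes %*% t(tf$rotation)
  structure(list(center = center, axes = axes,
                 half_extents = obb$half_extents,
                 corners = obb_corners(center, axes, obb$half_extents)),
            class = "oriented_bbox")
}
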