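#' Three-label encoding of an instance label map
#'
#' Converts a vertebra instance map into the body/boundary/background
#' representation used to train the segmentation branch and to keep
#' neighbouring vertebrae separable. Each instance is processed
#' independently: its eroded mask becomes the inner *body* label (1) and
#' the eroded-away remainder the *boundary* label (2). Erosion uses the
#' discrete sphere of radius `erosion_radius` in the voxel metric; the
#' default radius 1 is the 6-connected unit ball.
#'
#' Body and boundary partition each instance exactly: their union equals
#' the original foreground, voxel for voxel.
#'
#' @param lm a [labelmap()].
#' @param erosion_radius erosion radius in voxels (>= 1).
#' @return A [labelmap()]-like object of class `vertseg_threelabel` with
#'   values in \{0 background, 1 body, 2 boundary\} and attribute
#'   `erosion_radius`.
#' @export
encode_three_label <- function(lm, erosion_radius = 1) {
  stopifnot(inherits(lm, "vertseg_labelmap"))
  if (erosion_radius < 1) stop("erosion_radius must be >= 1")
  off <- ball_offsets(rep(erosion_radius, 3))
  out <- array(0L, dim(lm$values))
  for (lab in setdiff(sort(unique(as.vector(lm$values))), 0L)) {
    inst <- lm$values == lab
    body <- erode3(inst, off)
    out[body] <- 1L
    out[inst & !body] <- 2L
  }
  tlm <- labelmap(out, spacing = lm$spacing, origin = lm$origin)
  class(tlm) <- c("vertseg_threelabel", class(tlm))
  attr(tlm, "erosion_radius") <- erosion_radius
  tlm
}

#' Merge the three-label foreground back into a binary mask
#'
#' Inverse of [encode_three_label()] up to instance identity: returns the
#' union of body and boundary.
#'
#' @param tlm a three-label map from [encode_three_label()] (or any
#'   volume whose nonzero voxels are foreground).
#' @return Logical 3D array.
#' @export
merge_foreground <- function(tlm) {
  tlm$values != 0L
}

#' Center of mass of a vertebral body
#'
#' The localization target of a vertebra is the center of mass of its
#' *body*, obtained by morphologically opening the instance mask so that
#' the thin posterior processes are removed before averaging. If the
#' opening removes everything (tiny instance), the center of mass of the
#' unopened mask is used instead.
#'
#' @param instance_mask logical 3D array (one instance), axis order (z,y,x).
#' @param opening_radii opening radii in voxels, (z, y, x). The default
#'   (1 in z, 3 in-plane) removes processes 2-5 voxels thick.
#' @param spacing voxel spacing (mm).
#' @param origin volume origin (mm).
#' @return Numeric length-3 center (z, y, x) in mm.
#' @export
vertebral_body_center <- function(instance_mask, opening_radii = c(1, 3, 3),
                                  spacing = c(2, 0.977, 0.977),
                                  origin = c(0, 0, 0)) {
  if (!any(instance_mask != 0)) stop("empty instance mask")
  opened <- open3(instance_mask != 0, ball_offsets(opening_radii))
  if (!any(opened)) opened <- instance_mask != 0
  mask_center_mm(opened, spacing, origin)
}

#' Body centers of every instance in a label map
#'
#' @param lm a [labelmap()].
#' @inheritParams vertebral_body_center
#' @return Numeric matrix (k x 3) of centers in mm, one row per instance
#'   label 1..k (row i corresponds to label i).
#' @export
instance_body_centers <- function(lm, opening_radii = c(1, 3, 3)) {
  labs <- setdiff(sort(unique(as.vector(lm$values))), 0L)
  centers <- t(vapply(labs, function(l)
    vertebral_body_center(lm$values == l, opening_radii,
                          lm$spacing, lm$origin), numeric(3)))
  rownames(centers) <- labs
  centers
}
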