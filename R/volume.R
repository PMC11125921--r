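#' 3D scalar volume with voxel geometry
#'
#' A `vertseg_volume` wraps a numeric 3D array together with its voxel
#' spacing and origin. All arrays in this package use the axis order
#' (z, y, x) with z the cranio-caudal axis, so `dim(values)[1]` is the
#' number of axial slices. Spacing and origin are given in millimetres in
#' the same (z, y, x) order. The physical position of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3D array, axis order (z, y, x).
#' @param spacing numeric length-3 vector of strictly positive voxel sizes
#'   (mm), order (z, y, x).
#' @param origin numeric length-3 vector (mm), order (z, y, x).
#' @return An object of class `vertseg_volume`.
#' @examples
#' v <- volume(array(0, c(4, 5, 6)), spacing = c(2, 1, 1))
#' dim(v$values)
#' @export
volume <- function(values, spacing = c(2, 0.977, 0.977), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "vertseg_volume")
}

#' Instance label map
#'
#' A `vertseg_labelmap` is a [volume()] whose values are non-negative
#' integers: 0 is background and positive labels identify vertebra
#' instances, numbered 1..k from bottom (caudal) to top (cranial).
#'
#' @inheritParams volume
#' @return An object of classes `vertseg_labelmap`, `vertseg_volume`.
#' @export
labelmap <- function(values, spacing = c(2, 0.977, 0.977), origin = c(0, 0, 0)) {
  v <- volume(values, spacing, origin)
  vals <- v$values
  if (any(vals < 0) || any(vals != round(vals)))
    stop("label map values must be non-negative integers")
  storage.mode(v$values) <- "integer"
  class(v) <- c("vertseg_labelmap", "vertseg_volume")
  v
}

#' @export
print.vertseg_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels (z,y,x), spacing %.3f x %.3f x %.3f mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "vertseg_labelmap")) {
    labs <- setdiff(sort(unique(as.vector(x$values))), 0L)
    cat(sprintf("  %d instance(s): %s\n", length(labs),
                paste(labs, collapse = " ")))
  } else {
    cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

n_instances <- function(lm) {
  length(setdiff(unique(as.vector(lm$values)), 0L))
}

#' Convert voxel indices to physical coordinates
#'
#' @param idx numeric matrix (n x 3) of 1-based voxel indices in (z, y, x)
#'   order, or a length-3 vector.
#' @param vol a [volume()].
#' @return Matrix (n x 3) of physical positions in mm.
#' @export
voxel_to_mm <- function(idx, vol) {
  idx <- rbind_points(idx)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Convert physical coordinates to (fractional) voxel indices
#'
#' @param pts numeric matrix (n x 3) of positions in mm, (z, y, x) order.
#' @param vol a [volume()].
#' @return Matrix (n x 3) of 1-based, possibly fractional, voxel indices.
#' @export
mm_to_voxel <- function(pts, vol) {
  pts <- rbind_points(pts)
  sweep(sweep(pts, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1)
  if (ncol(p) != 3L) stop("points must have 3 columns (z, y, x)")
  p
}

#' Center of mass of a binary mask, in millimetres
#'
#' @param mask logical or 0/1 3D array in (z, y, x) order.
#' @param spacing voxel spacing (mm), (z, y, x).
#' @param origin volume origin (mm), (z, y, x).
#' @return Numeric length-3 vector (z, y, x) in mm.
#' @export
mask_center_mm <- function(mask, spacing = c(2, 0.977, 0.977),
                           origin = c(0, 0, 0)) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask has no center of mass")
  colMeans(sweep(sweep(w - 1, 2, spacing, `*`), 2, origin, `+`))
}

#' Read a NIfTI file as a volume or label map
#'
#' NIfTI stores arrays in (x, y, z) order; they are permuted to this
#' package's (z, y, x) convention on the way in.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param labels if `TRUE`, return a [labelmap()] (values rounded to
#'   integer), otherwise a [volume()].
#' @return A [volume()] or [labelmap()].
#' @export
read_volume <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 2, 1))
  sp <- rev(RNifti::pixdim(img)[1:3])
  if (labels) labelmap(round(arr), spacing = sp) else volume(arr, spacing = sp)
}

#' Write a volume or label map to NIfTI
#'
#' @param vol a [volume()] or [labelmap()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- aperm(vol$values, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# deterministic local RNG scope: run `expr` under `seed` and restore the
# caller's RNG state afterwards
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
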