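#' Structuring element offsets for a voxel-metric ellipsoidal ball
#'
#' Returns the integer offsets `(dz, dy, dx)` with
#' `(dz/rz)^2 + (dy/ry)^2 + (dx/rx)^2 <= 1`. With `radii = c(1, 1, 1)` this
#' is the 6-connected unit ball (the discrete sphere of radius one in the
#' voxel metric: the centre plus its six face neighbours).
#'
#' @param radii numeric length-3 (z, y, x) radii in voxels.
#' @return Integer matrix (n x 3) of offsets.
#' @export
ball_offsets <- function(radii = c(1, 1, 1)) {
  radii <- as.numeric(radii)
  if (length(radii) != 3L || any(radii < 0)) stop("radii must be 3 values >= 0")
  r <- floor(radii)
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  rr <- pmax(radii, 1e-9)
  keep <- (g$dz / rr[1])^2 + (g$dy / rr[2])^2 + (g$dx / rr[3])^2 <= 1 + 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

# shift a 3D array by integer offset d = (dz,dy,dx); out[v] = a[v + d],
# out-of-bounds filled with `fill`
shift3 <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    lo <- max(1L, 1L + d[ax]); hi <- min(dm[ax], dm[ax] + d[ax])
    if (lo > hi) return(out)
    src[[ax]] <- lo:hi
    dst[[ax]] <- (lo - d[ax]):(hi - d[ax])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binary erosion of a 3D mask
#'
#' @param mask logical 3D array.
#' @param offsets structuring-element offsets from [ball_offsets()].
#' @return Logical 3D array: voxels whose whole structuring element lies
#'   inside the mask. Out-of-volume neighbours count as background.
#' @export
erode3 <- function(mask, offsets = ball_offsets(c(1, 1, 1))) {
  mask <- mask != 0
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift3(mask, offsets[i, ], fill = FALSE)
  out
}

#' Binary dilation of a 3D mask
#'
#' @inheritParams erode3
#' @return Logical 3D array: union of the mask translated by every offset.
#' @export
dilate3 <- function(mask, offsets = ball_offsets(c(1, 1, 1))) {
  mask <- mask != 0
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift3(mask, -offsets[i, ], fill = FALSE)
  out
}

#' Morphological opening (erosion followed by dilation)
#'
#' @inheritParams erode3
#' @return Logical 3D array.
#' @export
open3 <- function(mask, offsets = ball_offsets(c(1, 1, 1))) {
  dilate3(erode3(mask, offsets), offsets)
}

#' Connected components of a 3D mask
#'
#' Deterministic labelling: components are numbered by the scan order
#' (z fastest) of their first voxel.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (face), 18 (face+edge) or 26 (full) neighbourhood.
#' @return Integer 3D array of component labels, 0 = background.
#' @export
connected_components <- function(mask, connectivity = 26) {
  mask <- mask != 0
  cpp_connected_components(mask, as.integer(connectivity))
}

#' Remove satellite components and fill internal cavities
#'
#' Keeps only the largest connected component of the mask, then fills any
#' cavity that is not connected to the volume border through background.
#' Used per instance after watershed separation.
#'
#' @param mask logical 3D array (one instance).
#' @param connectivity connectivity for the component analysis.
#' @return Logical 3D array.
#' @export
fill_islands_holes <- function(mask, connectivity = 26) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  cc <- connected_components(mask, connectivity)
  sizes <- tabulate(cc[cc > 0L])
  keep <- which.max(sizes)
  mask <- cc == keep
  # invert; background reachable from the border stays, enclosed cavities
  # become part of the object
  inv <- !mask
  cci <- connected_components(inv, connectivity)
  border_labels <- unique(c(cci[1, , ], cci[dim(cci)[1], , ],
                            cci[, 1, ], cci[, dim(cci)[2], ],
                            cci[, , 1], cci[, , dim(cci)[3]]))
  border_labels <- setdiff(border_labels, 0L)
  reachable <- array(cci %in% border_labels, dim(cci))
  mask | (inv & !reachable)
}
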