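#' Resample a volume onto a target voxel grid
#'
#' Intensity volumes are interpolated trilinearly; label maps use
#' nearest-neighbour so that the output value set stays a subset of the
#' input's. The physical extent is preserved to within one voxel and the
#' origin (the first voxel's center position) is kept.
#'
#' @param v a [volume()] or [labelmap()].
#' @param target_spacing target voxel size in mm, (z, y, x). The default
#'   is the working grid of the pipeline, 2 x 0.977 x 0.977 mm.
#' @param is_labels force nearest-neighbour resampling; defaults to `TRUE`
#'   for [labelmap()] inputs.
#' @return A resampled [volume()] or [labelmap()].
#' @export
resample_to_working_grid <- function(v, target_spacing = c(2, 0.977, 0.977),
                                     is_labels = inherits(v, "vertseg_labelmap")) {
  stopifnot(inherits(v, "vertseg_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  din <- dim(v$values)
  extent <- din * v$spacing
  dout <- pmax(round(extent / target_spacing), 1)
  if (any(dout < 1)) stop("zero-sized output grid")
  # fractional input indices of the output voxel centers, per axis
  fidx <- lapply(1:3, function(ax) {
    pos <- (seq_len(dout[ax]) - 1) * target_spacing[ax]
    pmin(pmax(pos / v$spacing[ax] + 1, 1), din[ax])
  })
  out <- array(0, dout)
  if (is_labels) {
    iz <- round(fidx[[1]]); iy <- round(fidx[[2]]); ix <- round(fidx[[3]])
    out[] <- v$values[iz, iy, ix]
    return(labelmap(out, spacing = target_spacing, origin = v$origin))
  }
  z0 <- pmin(floor(fidx[[1]]), din[1] - 1L); wz <- fidx[[1]] - z0
  y0 <- pmin(floor(fidx[[2]]), din[2] - 1L); wy <- fidx[[2]] - y0
  if (din[1] == 1L) { z0 <- rep(1, dout[1]); wz <- rep(0, dout[1]) }
  if (din[2] == 1L) { y0 <- rep(1, dout[2]); wy <- rep(0, dout[2]) }
  for (k in seq_len(dout[3])) {
    fx <- fidx[[3]][k]
    x0 <- min(floor(fx), max(din[3] - 1L, 1L)); wx <- fx - x0
    A <- if (din[3] == 1L) v$values[, , 1]
         else v$values[, , x0] * (1 - wx) + v$values[, , x0 + 1] * wx
    A <- matrix(A, din[1], din[2])
    B <- A[z0, , drop = FALSE] * (1 - wz) +
         A[pmin(z0 + 1, din[1]), , drop = FALSE] * wz
    out[, , k] <- sweep(B[, y0, drop = FALSE], 2, 1 - wy, `*`) +
                  sweep(B[, pmin(y0 + 1, din[2]), drop = FALSE], 2, wy, `*`)
  }
  volume(out, spacing = target_spacing, origin = v$origin)
}

#' Reference intensity statistics for normalization
#'
#' Computes the clipping bounds and Z-score statistics once over a
#' (training) set of volumes: the `lo_pct`/`hi_pct` percentiles of the
#' pooled intensities (linear interpolation between order statistics),
#' and the mean and standard deviation of the pooled values after
#' clipping. Test volumes are then normalized with these fixed statistics
#' via [clip_and_normalize()].
#'
#' @param volumes a [volume()] or list of volumes.
#' @param lo_pct,hi_pct clipping percentiles (default 0.5 and 99.5).
#' @return List `(lo, hi, mean, sd, lo_pct, hi_pct)`.
#' @export
compute_norm_stats <- function(volumes, lo_pct = 0.5, hi_pct = 99.5) {
  if (inherits(volumes, "vertseg_volume")) volumes <- list(volumes)
  if (lo_pct >= hi_pct) stop("lo_pct must be below hi_pct")
  pooled <- unlist(lapply(volumes, function(v) as.vector(v$values)))
  qs <- stats::quantile(pooled, c(lo_pct, hi_pct) / 100, names = FALSE,
                        type = 7)
  clipped <- pmin(pmax(pooled, qs[1]), qs[2])
  list(lo = qs[1], hi = qs[2], mean = mean(clipped), sd = stats::sd(clipped),
       lo_pct = lo_pct, hi_pct = hi_pct)
}

#' Clip and Z-score normalize a volume with fixed reference statistics
#'
#' Values are clipped to the reference percentile bounds, then shifted and
#' scaled by the reference mean and standard deviation. With fixed
#' statistics the operation is idempotent up to the clipping bounds'
#' images. The standard deviation is floored at `1e-6` to keep degenerate
#' (constant) reference sets finite.
#'
#' @param v a [volume()].
#' @param stats reference statistics from [compute_norm_stats()] or
#'   [read_norm_stats()].
#' @return A normalized [volume()].
#' @export
clip_and_normalize <- function(v, stats) {
  stopifnot(inherits(v, "vertseg_volume"))
  needed <- c("lo", "hi", "mean", "sd")
  if (!all(needed %in% names(stats))) stop("incomplete reference statistics")
  if (!is.finite(stats$sd)) stop("degenerate reference statistics")
  sd_f <- max(stats$sd, 1e-6)
  vals <- pmin(pmax(v$values, stats$lo), stats$hi)
  volume((vals - stats$mean) / sd_f, spacing = v$spacing, origin = v$origin)
}

#' @rdname compute_norm_stats
#' @param stats statistics list to serialize.
#' @param path JSON sidecar path (conventionally `norm_stats.json`).
#' @export
write_norm_stats <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname compute_norm_stats
#' @export
read_norm_stats <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Crop the vertebra volume of interest
#'
#' The VOI is anchored at the bottom on either the pelvis center of mass
#' (`pelvis_mask`), a user-supplied axial plane (`bottom_plane`), or the
#' first slice of the scan (`scan_bottom`). Axially (y, x) it is centered
#' on the pelvis center of mass in pelvis mode and on the scan center
#' otherwise. Portions of the requested box outside the scan are ignored
#' (the VOI is clipped to the scan bounds).
#'
#' @param v a [volume()].
#' @param anchor either the string `"scan_bottom"`, a list
#'   `list(mode = "bottom_plane", z = <slice index>)`, or a list
#'   `list(mode = "pelvis_mask", mask = <labelmap or logical array>)`.
#' @param crop_size requested VOI extents in voxels, (z, y, x). The
#'   defaults mirror a 256 x 256 axial crop with 128 slices.
#' @param top_limit optional highest slice index the VOI may reach.
#' @return List with `volume` (the cropped volume) and `voi`, a list with
#'   1-based `lower_corner`, `size` and `source`.
#' @export
crop_voi <- function(v, anchor = "scan_bottom", crop_size = c(128, 256, 256),
                     top_limit = NULL) {
  stopifnot(inherits(v, "vertseg_volume"))
  d <- dim(v$values)
  mode <- if (is.character(anchor)) anchor else anchor$mode
  if (mode == "pelvis_mask") {
    m <- anchor$mask
    mvals <- if (inherits(m, "vertseg_volume")) m$values else m
    if (!any(mvals != 0)) stop("empty pelvis mask")
    com <- colMeans(which(mvals != 0, arr.ind = TRUE))
    z_lo <- round(com[1])
    center_yx <- com[2:3]
  } else if (mode == "bottom_plane") {
    z_lo <- round(anchor$z)
    center_yx <- (d[2:3] + 1) / 2
  } else if (mode == "scan_bottom") {
    z_lo <- 1
    center_yx <- (d[2:3] + 1) / 2
  } else stop("unknown VOI anchor mode: ", mode)
  z_hi <- z_lo + crop_size[1] - 1
  if (!is.null(top_limit)) z_hi <- min(z_hi, top_limit)
  lo <- c(z_lo, round(center_yx - crop_size[2:3] / 2 + 1))
  hi <- c(z_hi, lo[2:3] + crop_size[2:3] - 1)
  lo <- unname(pmax(lo, 1))
  hi <- unname(pmin(hi, d))
  if (any(hi < lo)) stop("VOI does not intersect the scan")
  sub <- v$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- v$origin + (lo - 1) * v$spacing
  out <- if (inherits(v, "vertseg_labelmap"))
    labelmap(sub, spacing = v$spacing, origin = origin)
  else volume(sub, spacing = v$spacing, origin = origin)
  list(volume = out,
       voi = list(lower_corner = lo, size = hi - lo + 1, source = mode))
}
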