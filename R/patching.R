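#' Build the overlapping patch grid over a VOI
#'
#' Patch origins form a regular lattice with stride
#' `patch_size * (1 - overlap_fraction)` (which must be a whole number of
#' voxels). The last patch per axis is clamped so its far face coincides
#' with the VOI boundary, guaranteeing that every VOI voxel is covered by
#' at least one patch. If the patch exceeds the VOI along an axis, a
#' single patch clamped to the VOI extent is used (with a warning).
#'
#' @param voi_size VOI extents in voxels, (z, y, x).
#' @param patch_size patch extents in voxels; the default 32 x 48 x 48 is
#'   the network's native input size.
#' @param overlap_fraction fractional overlap between neighbouring
#'   patches in every direction (default 0.5).
#' @return A `vertseg_patch_grid`: list with `origins` (n x 3 matrix of
#'   1-based lower corners), `patch_size`, `overlap_fraction`, `voi_size`.
#' @export
build_patch_grid <- function(voi_size, patch_size = c(32, 48, 48),
                             overlap_fraction = 0.5) {
  voi_size <- as.integer(voi_size); patch_size <- as.integer(patch_size)
  if (any(patch_size > voi_size)) {
    warning("patch larger than VOI; using a single clamped patch")
    patch_size <- pmin(patch_size, voi_size)
  }
  stride <- patch_size * (1 - overlap_fraction)
  if (any(stride != round(stride)) || any(stride < 1))
    stop("overlap_fraction must give an integer stride >= 1")
  stride <- as.integer(round(stride))
  ax_pos <- lapply(1:3, function(a) {
    last <- voi_size[a] - patch_size[a] + 1L
    sort(unique(c(seq.int(1L, last, by = stride[a]), last)))
  })
  origins <- as.matrix(expand.grid(z = ax_pos[[1]], y = ax_pos[[2]],
                                   x = ax_pos[[3]]))
  structure(list(origins = origins, patch_size = patch_size,
                 overlap_fraction = overlap_fraction, voi_size = voi_size),
            class = "vertseg_patch_grid")
}

#' @export
print.vertseg_patch_grid <- function(x, ...) {
  cat(sprintf("<patch grid> %d patches of %s over VOI %s, overlap %.0f%%\n",
              nrow(x$origins), paste(x$patch_size, collapse = "x"),
              paste(x$voi_size, collapse = "x"), 100 * x$overlap_fraction))
  invisible(x)
}

# physical position (mm) of a patch center
patch_center_mm <- function(patch_origin, patch_size, spacing,
                            origin = c(0, 0, 0)) {
  origin + (patch_origin - 1 + (patch_size - 1) / 2) * spacing
}

#' Localization ground truth for one patch: the 1x12 target
#'
#' Builds the regression target of the localization head: offsets (mm)
#' from the patch center to the body centers of three consecutive
#' vertebrae (top, mid, bottom) plus one confidence score each. The
#' confidence of a vertebra is the fraction of its total volume lying
#' inside the patch; a confidence of 0 marks a neighbour that is absent
#' from the patch, whose position is extrapolated.
#'
#' Mid-center selection by number of visible vertebrae: one visible - it
#' is the mid; two - the lower one; three - the middle one; more than
#' three - the lowest-confidence vertebra is dropped repeatedly (ties:
#' drop the topmost) until three remain, whose middle is the mid. The top
#' and bottom slots are the anatomical neighbours of the mid; an absent
#' neighbour's position is mirrored from the opposite present neighbour,
#' or offset by `default_gap` along z when both are absent.
#'
#' @param patch_origin 1-based lower corner of the patch (z, y, x).
#' @param patch_size patch extents in voxels.
#' @param lm the instance [labelmap()] (on the same grid as the patch).
#' @param body_centers matrix (k x 3) of per-instance body centers in mm
#'   (row i = label i), e.g. from [instance_body_centers()].
#' @param default_gap fallback inter-center z-gap (mm) for extrapolation
#'   when no neighbour is visible.
#' @return A `vertseg_loc_target`: list with `offsets` (3 x 3 matrix, rows
#'   top/mid/bottom, mm), `confidences` (length 3, order top/mid/bottom),
#'   `labels` (the instance labels pointed to) and `patch_center` (mm).
#'   `as.numeric()` flattens it to the 12-vector in the order
#'   (top offset, mid offset, bottom offset, conf top, conf mid,
#'   conf bottom).
#' @export
localization_target <- function(patch_origin, patch_size, lm, body_centers,
                                default_gap = 30) {
  stopifnot(inherits(lm, "vertseg_labelmap"))
  hi <- pmin(patch_origin + patch_size - 1, dim(lm$values))
  sub <- lm$values[patch_origin[1]:hi[1], patch_origin[2]:hi[2],
                   patch_origin[3]:hi[3]]
  totals <- tabulate(lm$values[lm$values > 0L])
  inside <- tabulate(sub[sub > 0L], nbins = length(totals))
  visible <- which(inside > 0L)
  if (length(visible) == 0L)
    stop("patch contains no instance voxels; not a localization target")
  conf_all <- inside / totals
  # mid-center selection rules
  sel <- visible
  while (length(sel) > 3L) {
    worst <- min(conf_all[sel])
    cand <- sel[conf_all[sel] == worst]
    sel <- setdiff(sel, max(cand)) # tie-break: drop the topmost
  }
  mid <- if (length(sel) == 1L) sel
         else if (length(sel) == 2L) min(sel)
         else sort(sel)[2]
  slots <- c(top = mid + 1L, mid = mid, bottom = mid - 1L)
  pc <- patch_center_mm(patch_origin, patch_size, lm$spacing, lm$origin)
  pos <- matrix(NA_real_, 3, 3,
                dimnames = list(c("top", "mid", "bottom"), c("z", "y", "x")))
  confs <- c(top = 0, mid = conf_all[mid], bottom = 0)
  pos["mid", ] <- body_centers[mid, ]
  for (s in c("top", "bottom")) {
    lab <- slots[[s]]
    if (lab %in% visible) {
      pos[s, ] <- body_centers[lab, ]
      confs[[s]] <- conf_all[lab]
    }
  }
  sign_of <- c(top = 1, bottom = -1)
  for (s in c("top", "bottom")) {
    if (!is.na(pos[s, 1])) next
    other <- setdiff(c("top", "bottom"), s)
    pos[s, ] <- if (!is.na(pos[other, 1]))
      2 * pos["mid", ] - pos[other, ]         # mirror the present neighbour
    else pos["mid", ] + sign_of[[s]] * c(default_gap, 0, 0)
  }
  structure(list(offsets = sweep(pos, 2, pc, `-`), confidences = confs,
                 labels = slots, patch_center = pc),
            class = "vertseg_loc_target")
}

#' @export
as.double.vertseg_loc_target <- function(x, ...) {
  unname(c(x$offsets["top", ], x$offsets["mid", ], x$offsets["bottom", ],
           x$confidences[["top"]], x$confidences[["mid"]],
           x$confidences[["bottom"]]))
}

#' Sample a training batch of patch origins
#'
#' At least `ceil(batch_size * vertebra_fraction)` of the returned patches
#' intersect vertebra voxels; the remainder is drawn uniformly from the
#' whole grid. Sampling is with replacement and seeded.
#'
#' @param grid a [build_patch_grid()] result.
#' @param lm the instance [labelmap()] covering the VOI.
#' @param batch_size number of patches (>= 2).
#' @param vertebra_fraction minimum fraction of vertebra-containing
#'   patches (default 0.5, the balanced-batch rule).
#' @param seed integer seed.
#' @return Integer matrix (batch_size x 3) of patch origins.
#' @export
sample_training_batch <- function(grid, lm, batch_size = 32,
                                  vertebra_fraction = 0.5, seed = 1L) {
  if (batch_size < 2) stop("batch_size must be >= 2")
  has_vert <- patch_has_foreground(grid, lm$values != 0L)
  cand <- which(has_vert)
  if (!length(cand)) stop("no patch intersects a vertebra")
  n_v <- ceiling(batch_size * vertebra_fraction)
  with_rng(seed, {
    idx <- c(sample(cand, n_v, replace = TRUE),
             sample(nrow(grid$origins), batch_size - n_v, replace = TRUE))
    grid$origins[idx, , drop = FALSE]
  })
}

# logical vector: does each grid patch contain any TRUE voxel of `mask`
patch_has_foreground <- function(grid, mask) {
  vapply(seq_len(nrow(grid$origins)), function(i) {
    o <- grid$origins[i, ]; h <- o + grid$patch_size - 1
    any(mask[o[1]:h[1], o[2]:h[2], o[3]:h[3]])
  }, logical(1))
}

#' Stitch per-patch class probabilities into a three-label map
#'
#' Overlapping probabilities are averaged voxelwise over all covering
#' patches, then the class with maximal mean probability is taken
#' (background, body, boundary; ties resolved toward the lower class
#' code).
#'
#' @param patches list of arrays `(z, y, x, class)` of class
#'   probabilities, one per grid origin, in grid order.
#' @param grid the [build_patch_grid()] the patches came from.
#' @param spacing,origin geometry of the output map (mm).
#' @return A three-label map (class `vertseg_threelabel`).
#' @export
stitch_predictions <- function(patches, grid, spacing = c(2, 0.977, 0.977),
                               origin = c(0, 0, 0)) {
  n <- nrow(grid$origins)
  if (length(patches) != n)
    stop("need exactly one probability block per grid origin")
  nc <- dim(patches[[1]])[4]
  acc <- array(0, c(grid$voi_size, nc))
  cnt <- array(0, grid$voi_size)
  for (i in seq_len(n)) {
    o <- grid$origins[i, ]; h <- o + grid$patch_size - 1
    acc[o[1]:h[1], o[2]:h[2], o[3]:h[3], ] <-
      acc[o[1]:h[1], o[2]:h[2], o[3]:h[3], , drop = FALSE] + patches[[i]]
    cnt[o[1]:h[1], o[2]:h[2], o[3]:h[3]] <-
      cnt[o[1]:h[1], o[2]:h[2], o[3]:h[3]] + 1
  }
  if (any(cnt == 0)) stop("uncovered VOI voxels; inconsistent grid")
  nvox <- prod(grid$voi_size)
  probs <- matrix(acc, nvox, nc) / as.vector(cnt)
  cls <- max.col(probs, ties.method = "first") - 1L
  tlm <- labelmap(array(cls, grid$voi_size), spacing = spacing,
                  origin = origin)
  class(tlm) <- c("vertseg_threelabel", class(tlm))
  tlm
}

#' Average instance volume of a label map
#'
#' The typical vertebra volume (in voxels) used by the 15 percent gating
#' rule of the localization branch.
#'
#' @param lm a [labelmap()] (or list of label maps, pooled).
#' @return Mean number of voxels per instance.
#' @export
mean_vertebra_volume <- function(lm) {
  if (inherits(lm, "vertseg_labelmap")) lm <- list(lm)
  sizes <- unlist(lapply(lm, function(l) {
    v <- l$values
    tabulate(v[v > 0L])
  }))
  mean(sizes[sizes > 0])
}
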