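#' Signed Euclidean distance map of a binary mask
#'
#' Exact Euclidean distance (mm, anisotropic spacing respected) to the
#' mask surface, negative inside the mask and positive outside: the value
#' at an inside voxel is minus its distance to the nearest background
#' voxel, at an outside voxel its distance to the nearest mask voxel.
#'
#' @param mask logical 3D array (z, y, x).
#' @param spacing voxel spacing in mm.
#' @return Numeric 3D array of signed distances (mm).
#' @export
signed_distance_map <- function(mask, spacing = c(2, 0.977, 0.977)) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  d_out <- cpp_edt(mask, as.numeric(spacing))
  d_in <- cpp_edt(!mask, as.numeric(spacing))
  d_out - d_in
}

#' Shift centers to local minima of the distance map
#'
#' Each center moves to the argmin of the distance map inside its
#' `window^3` voxel neighbourhood, repeated until a fixed point is
#' reached (at most `max_iter` times). Ties go to the first voxel in scan
#' order. Centers are refined independently.
#'
#' @param centers numeric matrix (k x 3) of positions in mm (z, y, x).
#' @param dmap signed distance map from [signed_distance_map()].
#' @param spacing,origin geometry of `dmap`.
#' @param window odd window edge length in voxels (default 5).
#' @param max_iter iteration cap (default 10).
#' @return Matrix (k x 3) of refined centers in mm.
#' @export
refine_centers <- function(centers, dmap, spacing = c(2, 0.977, 0.977),
                           origin = c(0, 0, 0), window = 5, max_iter = 10) {
  centers <- rbind_points(centers)
  d <- dim(dmap)
  h <- (window - 1) %/% 2
  out <- centers
  for (i in seq_len(nrow(centers))) {
    idx <- pmin(pmax(round((centers[i, ] - origin) / spacing + 1), 1), d)
    for (it in seq_len(max_iter)) {
      zr <- max(1, idx[1] - h):min(d[1], idx[1] + h)
      yr <- max(1, idx[2] - h):min(d[2], idx[2] + h)
      xr <- max(1, idx[3] - h):min(d[3], idx[3] + h)
      sub <- dmap[zr, yr, xr, drop = FALSE]
      m <- which(sub == min(sub), arr.ind = TRUE)[1, , drop = TRUE]
      new_idx <- c(zr[m[1]], yr[m[2]], xr[m[3]])
      if (all(new_idx == idx)) break
      idx <- new_idx
    }
    out[i, ] <- origin + (idx - 1) * spacing
  }
  out
}

#' Split a body mask into instances by seeded watershed
#'
#' Priority-flood watershed on the signed distance map restricted to the
#' body mask: flooding starts at the seed voxels and proceeds in
#' ascending distance-map order (ties broken by insertion order, i.e.
#' deterministic scan order). Mask voxels unreachable from any seed are
#' assigned to the region of the nearest seed.
#'
#' @param body_mask logical 3D array of the (merged) body label.
#' @param seeds numeric matrix (k x 3) of seed positions in mm; every
#'   seed must lie inside the mask.
#' @param spacing,origin voxel geometry.
#' @param dmap optional precomputed signed distance map of `body_mask`.
#' @param connectivity flooding connectivity (default 26).
#' @return A [labelmap()] with labels 1..k in seed order.
#' @export
split_watershed <- function(body_mask, seeds, spacing = c(2, 0.977, 0.977),
                            origin = c(0, 0, 0), dmap = NULL,
                            connectivity = 26) {
  body_mask <- body_mask != 0
  seeds <- rbind_points(seeds)
  d <- dim(body_mask)
  if (is.null(dmap)) dmap <- signed_distance_map(body_mask, spacing)
  idx <- round(sweep(sweep(seeds, 2, origin, `-`), 2, spacing, `/`)) + 1
  if (any(idx < 1) || any(sweep(idx, 2, d, `>`)))
    stop("seed outside the volume")
  lin <- (idx[, 1] - 1) + d[1] * ((idx[, 2] - 1) + d[2] * (idx[, 3] - 1))
  if (any(!body_mask[lin + 1])) stop("seed outside the body mask")
  lab <- cpp_watershed(dmap, body_mask, as.integer(lin),
                       seq_len(nrow(seeds)), as.integer(connectivity))
  unreached <- body_mask & lab == 0L
  if (any(unreached)) {
    w <- which(unreached, arr.ind = TRUE)
    pos <- sweep(sweep(w - 1, 2, spacing, `*`), 2, origin, `+`)
    d2 <- vapply(seq_len(nrow(seeds)), function(j)
      colSums((t(pos) - seeds[j, ])^2), numeric(nrow(pos)))
    if (!is.matrix(d2)) d2 <- matrix(d2, nrow = nrow(pos))
    lab[unreached] <- max.col(-d2, ties.method = "first")
  }
  labelmap(lab, spacing = spacing, origin = origin)
}

#' Grow instance labels back over the boundary shell
#'
#' After the watershed has partitioned the body label, the instances are
#' dilated one voxel at a time, restricted to the original
#' body-plus-boundary foreground so that no voxel outside it is ever
#' labeled. A contested voxel goes to the label with the most
#' face-adjacent claimant voxels (ties to the lower label). Iteration
#' stops at convergence or after `max_rounds` rounds.
#'
#' @param labels a [labelmap()] of watershed instances (subset of the
#'   body region).
#' @param tlm the three-label map whose foreground bounds the growth.
#' @param max_rounds dilation round cap (default 5).
#' @return A [labelmap()] covering body and recovered boundary voxels.
#' @export
recover_boundary <- function(labels, tlm, max_rounds = 5) {
  stopifnot(inherits(labels, "vertseg_labelmap"))
  allowed <- merge_foreground(tlm)
  lab <- labels$values
  face <- ball_offsets(c(1, 1, 1))
  face <- face[rowSums(abs(face)) == 1L, , drop = FALSE]
  for (r in seq_len(max_rounds)) {
    free <- allowed & lab == 0L
    if (!any(free)) break
    labs_present <- setdiff(sort(unique(as.vector(lab))), 0L)
    votes <- array(0L, c(dim(lab), length(labs_present)))
    for (li in seq_along(labs_present)) {
      cur <- lab == labs_present[li]
      cnt <- array(0L, dim(lab))
      for (i in seq_len(nrow(face)))
        cnt <- cnt + shift3(cur, face[i, ], fill = FALSE)
      votes[, , , li] <- cnt
    }
    nvox <- prod(dim(lab))
    vm <- matrix(votes, nvox, length(labs_present))
    vm[!as.vector(free), ] <- 0L
    best <- max.col(vm, ties.method = "first")
    take <- as.vector(free) & rowSums(vm) > 0L
    if (!any(take)) break
    lab[take] <- labs_present[best[take]]
  }
  labelmap(lab, spacing = labels$spacing, origin = labels$origin)
}

#' Recover missed vertebrae from unlabeled foreground
#'
#' Connected components of the three-label foreground that carry no
#' instance label are candidate missed vertebrae. From largest to
#' smallest, each component's center of mass is inserted into the current
#' z-sorted center list; if the clustering score does not decrease
#' (CS(k+1) >= CS(k)) the component is accepted as a new instance.
#' Acceptance stops once 18 instances exist. Finally instances are
#' relabeled bottom to top.
#'
#' @param labels current instance [labelmap()].
#' @param tlm three-label map the labels were derived from.
#' @param model a [distance_model()] for the score.
#' @param max_instances hard cap on the instance count (default 18).
#' @param min_component_voxels components smaller than this are ignored
#'   as noise (default 10).
#' @param connectivity component connectivity (default 26).
#' @return List with `labels` (relabeled [labelmap()]), `provenance`
#'   (per final label, `"clustered"` or `"recovered"`) and `n_recovered`.
#' @export
recover_missing <- function(labels, tlm, model, max_instances = 18,
                            min_component_voxels = 10, connectivity = 26) {
  stopifnot(inherits(labels, "vertseg_labelmap"))
  lab <- labels$values
  fg <- merge_foreground(tlm)
  unl <- fg & lab == 0L
  prov <- rep("clustered", n_instances(labels))
  if (any(unl)) {
    cc <- connected_components(unl, connectivity)
    sizes <- tabulate(cc[cc > 0L])
    order_cc <- order(sizes, decreasing = TRUE)
    current <- instance_centers_of_mass(lab, labels$spacing, labels$origin)
    k <- nrow(current)
    next_label <- max(lab) + 1L
    for (ci in order_cc) {
      if (k >= max_instances) break
      if (sizes[ci] < min_component_voxels) next
      comp <- cc == ci
      cmm <- mask_center_mm(comp, labels$spacing, labels$origin)
      cs_old <- if (k >= 3) clustering_score(current, model) else -Inf
      cs_new <- tryCatch(clustering_score(rbind(current, cmm), model),
                         error = function(e) -Inf)
      if (cs_new >= cs_old && is.finite(cs_new)) {
        lab[comp] <- next_label
        prov <- c(prov, "recovered")
        current <- rbind(current, cmm)
        next_label <- next_label + 1L
        k <- k + 1L
      }
    }
  }
  out <- relabel_bottom_to_top(labelmap(lab, labels$spacing, labels$origin))
  perm <- attr(out, "permutation")
  list(labels = out, provenance = prov[perm],
       n_recovered = sum(prov == "recovered"))
}

# k x 3 matrix of per-instance centers of mass (mm), row i = label i
instance_centers_of_mass <- function(lab, spacing, origin) {
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  t(vapply(labs, function(l) mask_center_mm(lab == l, spacing, origin),
           numeric(3)))
}

#' Renumber instances from bottom to top
#'
#' Instances are relabeled 1..k by ascending center-of-mass z (ties by y
#' then x); voxel geometry is unchanged. The permutation applied (old
#' label order of the new labels) is attached as attribute
#' `"permutation"`.
#'
#' @param labels a [labelmap()].
#' @return The relabeled [labelmap()].
#' @export
relabel_bottom_to_top <- function(labels) {
  stopifnot(inherits(labels, "vertseg_labelmap"))
  lab <- labels$values
  old <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(old)) return(labels)
  coms <- t(vapply(old, function(l)
    mask_center_mm(lab == l, labels$spacing, labels$origin), numeric(3)))
  ord <- order(coms[, 1], coms[, 2], coms[, 3])
  lut <- integer(max(old))
  lut[old[ord]] <- seq_along(old)
  new_lab <- array(0L, dim(lab))
  nz <- lab > 0L
  new_lab[nz] <- lut[lab[nz]]
  out <- labelmap(new_lab, labels$spacing, labels$origin)
  attr(out, "permutation") <- ord
  out
}
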