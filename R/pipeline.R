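#' Pipeline configuration for end-to-end scan segmentation
#'
#' Bundles everything [segment_scan()] needs: the trained model, the
#' inter-vertebral distance model, normalization statistics, VOI
#' definition and the post-processing parameters. Every run returns the
#' resolved configuration alongside its outputs.
#'
#' @param model a trained [build_model()] network (may be `NULL` when an
#'   oracle predictor is supplied to [segment_scan()]).
#' @param dist_model a [distance_model()].
#' @param norm_stats reference statistics from [compute_norm_stats()];
#'   `NULL` skips normalization (already-normalized input).
#' @param mean_vertebra_volume typical vertebra volume (voxels) for the
#'   15 percent vote gate.
#' @param anchor VOI anchor passed to [crop_voi()].
#' @param crop_size VOI extents in voxels.
#' @param top_limit optional top slice bound of the VOI.
#' @param patch_size,overlap_fraction patch grid settings; a `NULL`
#'   patch size resolves to the model's native patch, or 32 x 48 x 48
#'   when an oracle predictor is used.
#' @param target_spacing working grid voxel size (mm); `NULL` skips
#'   resampling.
#' @param loc_gate_fraction fraction of the mean vertebra volume a
#'   patch's predicted foreground must reach to cast center votes.
#' @param conf_floor predicted confidences below this are discarded
#'   before clustering (near-zero weights destabilize k-means).
#' @param k_range candidate vertebra-count range.
#' @param exclusion optional vote exclusion region (see [select_k()]).
#' @param erosion_radius three-label erosion radius used in training.
#' @param seed seed for the clustering initialization.
#' @return A `vertseg_pipeline_config`.
#' @export
pipeline_config <- function(model = NULL, dist_model, norm_stats = NULL,
                            mean_vertebra_volume,
                            anchor = "scan_bottom",
                            crop_size = c(128, 256, 256), top_limit = NULL,
                            patch_size = NULL,
                            overlap_fraction = 0.5,
                            target_spacing = c(2, 0.977, 0.977),
                            loc_gate_fraction = 0.15, conf_floor = 0.01,
                            k_range = c(3, 19), exclusion = NULL,
                            erosion_radius = 1, seed = 1L) {
  structure(as.list(environment()), class = "vertseg_pipeline_config")
}

#' Oracle patch predictor from ground-truth labels
#'
#' Replaces the network by its ideal output: one-hot probabilities of the
#' ground-truth three-label map and exact localization targets. Used to
#' exercise and validate the post-processing chain in isolation.
#'
#' @param gt_labels ground-truth instance [labelmap()] on the working
#'   grid (after any resampling, before VOI cropping).
#' @param erosion_radius three-label erosion radius.
#' @return A function `(patch_values, patch_origin, patch_size) -> list(
#'   probs, loc)` with the same contract as [predict_patch()];
#'   `patch_origin` is given in working-grid voxel coordinates.
#' @export
make_oracle_predictor <- function(gt_labels, erosion_radius = 1) {
  tlm <- encode_three_label(gt_labels, erosion_radius)
  centers <- instance_body_centers(gt_labels)
  function(patch_values, patch_origin, patch_size) {
    cls <- extract_patch(tlm$values, patch_origin, patch_size)
    probs <- array(0, c(dim(cls), 3L))
    for (c in 0:2) probs[, , , c + 1L] <- (cls == c) * 1
    loc <- tryCatch(
      as.numeric(localization_target(patch_origin, patch_size, gt_labels,
                                     centers)),
      error = function(e) c(rep(0, 9), 0, 0, 0))
    list(probs = probs, loc = loc)
  }
}

#' Post-process a three-label segmentation into vertebra instances
#'
#' The model-based second half of the pipeline: select the vertebra count
#' from the weighted center votes, refine the centers on the signed
#' distance map of the body label, split the body mask by seeded
#' watershed, grow the instances back over the boundary shell, recover
#' missed vertebrae from unlabeled foreground, clean islands and holes
#' per instance, and relabel bottom to top.
#'
#' @param tlm three-label map (class `vertseg_threelabel`).
#' @param votes tibble of center votes (`z`, `y`, `x`, `weight`, mm).
#' @param dist_model a [distance_model()].
#' @param k_range,exclusion,seed passed to [select_k()].
#' @return List with `labels` (instance [labelmap()]), `k`, `provenance`,
#'   `cluster` (the [select_k()] result) and `log` (stage counts).
#' @export
postprocess_segmentation <- function(tlm, votes, dist_model,
                                     k_range = c(3, 19), exclusion = NULL,
                                     seed = 1L) {
  cluster <- select_k(votes, dist_model, k_range = k_range,
                      exclusion = exclusion, seed = seed)
  body <- tlm$values == 1L
  if (!any(body)) stop("empty body label; nothing to split")
  dmap <- signed_distance_map(body, tlm$spacing)
  centers <- refine_centers(cluster$centers, dmap, tlm$spacing, tlm$origin)
  centers <- snap_to_mask(centers, body, tlm$spacing, tlm$origin)
  ws <- split_watershed(body, centers, tlm$spacing, tlm$origin, dmap = dmap)
  grown <- recover_boundary(ws, tlm)
  rec <- recover_missing(grown, tlm, dist_model)
  lab <- rec$labels$values
  for (l in seq_len(max(lab, 0L))) {
    inst <- lab == l
    if (!any(inst)) next
    cleaned <- fill_islands_holes(inst)
    lab[inst & !cleaned] <- 0L
    lab[cleaned & lab == 0L] <- l
  }
  out <- relabel_bottom_to_top(labelmap(lab, tlm$spacing, tlm$origin))
  list(labels = out, k = n_instances(out),
       provenance = rec$provenance[attr(out, "permutation")],
       cluster = cluster,
       log = list(votes_used = cluster$votes_used, kopti = cluster$kopti,
                  n_recovered = rec$n_recovered))
}

# move any center that does not fall on a mask voxel to the nearest one
snap_to_mask <- function(centers, mask, spacing, origin) {
  d <- dim(mask)
  idx <- round(sweep(sweep(centers, 2, origin, `-`), 2, spacing, `/`)) + 1
  idx <- pmax(pmin(idx, matrix(d, nrow(idx), 3, byrow = TRUE)), 1)
  off <- which(!mask[idx])
  if (length(off)) {
    fg <- which(mask, arr.ind = TRUE)
    fg_mm <- sweep(sweep(fg - 1, 2, spacing, `*`), 2, origin, `+`)
    for (i in off) {
      d2 <- colSums((t(fg_mm) - centers[i, ])^2)
      centers[i, ] <- fg_mm[which.min(d2), ]
    }
  }
  centers
}

#' Segment all vertebrae in a CT scan
#'
#' Full pipeline: resample to the working grid, clip and normalize, crop
#' the VOI, run the network patch-wise (50 percent overlap), stitch the
#' three-label probabilities, accumulate weighted center votes from every
#' patch whose predicted foreground passes the volume gate (three votes
#' per patch), then run [postprocess_segmentation()]. The instance map is
#' returned on the input scan grid (nearest-neighbour inverse
#' resampling).
#'
#' @param ct a [volume()].
#' @param cfg a [pipeline_config()].
#' @param predictor optional oracle predictor (see
#'   [make_oracle_predictor()]); defaults to the configured model.
#' @return List with `labels` (instance [labelmap()] on the input grid),
#'   `labels_voi` (on the working VOI grid), `k`, `provenance`,
#'   `cluster`, `voi` and `log`.
#' @export
segment_scan <- function(ct, cfg, predictor = NULL) {
  stopifnot(inherits(cfg, "vertseg_pipeline_config"))
  if (is.null(predictor) && is.null(cfg$model))
    stop("no trained model in the pipeline config and no predictor given")
  work <- ct
  if (!is.null(cfg$target_spacing) &&
      !isTRUE(all.equal(ct$spacing, cfg$target_spacing)))
    work <- resample_to_working_grid(work, cfg$target_spacing)
  if (!is.null(cfg$norm_stats))
    work <- clip_and_normalize(work, cfg$norm_stats)
  cr <- crop_voi(work, cfg$anchor, cfg$crop_size, cfg$top_limit)
  voi <- cr$volume
  patch_size <- cfg$patch_size
  if (is.null(patch_size))
    patch_size <- if (!is.null(cfg$model)) cfg$model$cfg$patch_size
                  else c(32, 48, 48)
  grid <- build_patch_grid(dim(voi$values), patch_size,
                           cfg$overlap_fraction)
  n <- nrow(grid$origins)
  probs <- vector("list", n)
  vote_rows <- list()
  for (i in seq_len(n)) {
    o <- grid$origins[i, ]
    patch <- extract_patch(voi$values, o, grid$patch_size)
    pred <- if (is.null(predictor)) predict_patch(cfg$model, patch)
            else predictor(patch, o + cr$voi$lower_corner - 1L,
                           grid$patch_size)
    probs[[i]] <- pred$probs
    cls <- max.col(matrix(pred$probs, ncol = 3), ties.method = "first") - 1L
    if (loc_gate(sum(cls != 0L), cfg$loc_gate_fraction,
                 cfg$mean_vertebra_volume)) {
      pc <- patch_center_mm(o, grid$patch_size, voi$spacing, voi$origin)
      offs <- matrix(pred$loc[1:9], 3, 3, byrow = TRUE)
      confs <- pred$loc[10:12]
      keep <- confs >= cfg$conf_floor
      if (any(keep))
        vote_rows[[length(vote_rows) + 1L]] <- tibble::tibble(
          z = pc[1] + offs[keep, 1], y = pc[2] + offs[keep, 2],
          x = pc[3] + offs[keep, 3], weight = pmin(confs[keep], 1))
    }
  }
  if (!length(vote_rows)) stop("no patch passed the vote gate")
  votes <- do.call(rbind, vote_rows)
  tlm <- stitch_predictions(probs, grid, voi$spacing, voi$origin)
  post <- postprocess_segmentation(tlm, votes, cfg$dist_model,
                                   k_range = cfg$k_range,
                                   exclusion = cfg$exclusion,
                                   seed = cfg$seed)
  labels_full <- map_labels_to_grid(post$labels, dim(ct$values),
                                    ct$spacing, ct$origin)
  list(labels = labels_full, labels_voi = post$labels, k = post$k,
       provenance = post$provenance, cluster = post$cluster, voi = cr$voi,
       log = c(post$log, list(n_patches = n, n_votes = nrow(votes))))
}

# nearest-neighbour transfer of a label map onto an arbitrary grid
map_labels_to_grid <- function(labels, target_dims, target_spacing,
                               target_origin) {
  d <- dim(labels$values)
  ax <- lapply(1:3, function(a) {
    pos <- target_origin[a] + (seq_len(target_dims[a]) - 1) * target_spacing[a]
    idx <- round((pos - labels$origin[a]) / labels$spacing[a]) + 1
    ifelse(idx >= 1 & idx <= d[a], idx, NA_integer_)
  })
  out <- array(0L, target_dims)
  okz <- !is.na(ax[[1]]); oky <- !is.na(ax[[2]]); okx <- !is.na(ax[[3]])
  out[okz, oky, okx] <- labels$values[ax[[1]][okz], ax[[2]][oky],
                                      ax[[3]][okx]]
  labelmap(out, spacing = target_spacing, origin = target_origin)
}
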