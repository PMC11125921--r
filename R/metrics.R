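#' Dice overlap coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical 3D arrays on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks are on different grids")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# foreground voxels with at least one face-neighbour outside the mask
# (voxels on the volume border count as surface)
surface_voxels <- function(mask) {
  mask <- mask != 0
  face <- ball_offsets(c(1, 1, 1))
  face <- face[rowSums(abs(face)) == 1L, , drop = FALSE]
  inner <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(face)))
    inner <- inner & shift3(mask, face[i, ], fill = FALSE)
  mask & !inner
}

#' Surface-distance error metrics between two segmentations
#'
#' Surface voxels are foreground voxels with a face-adjacent background
#' voxel. `du` is the mean distance (mm) from each predicted surface
#' voxel to the nearest reference surface voxel; `ds` is the same mean
#' with a negative sign for predicted surface voxels lying strictly
#' inside the reference (so a positive `ds` indicates
#' over-segmentation). `hd` is the symmetric Hausdorff distance, the
#' larger of the two directed surface-distance maxima.
#'
#' @param pred,ref nonempty logical 3D arrays on the same grid.
#' @param spacing voxel spacing (mm).
#' @return Named list `(ds, du, hd)` in mm.
#' @export
surface_distances <- function(pred, ref, spacing = c(2, 0.977, 0.977)) {
  if (!identical(dim(pred), dim(ref))) stop("masks are on different grids")
  pred <- pred != 0; ref <- ref != 0
  if (!any(pred) || !any(ref)) stop("surface distances need nonempty masks")
  ps <- surface_voxels(pred)
  rs <- surface_voxels(ref)
  d_to_ref <- cpp_edt(rs, as.numeric(spacing))
  d_to_pred <- cpp_edt(ps, as.numeric(spacing))
  dp <- d_to_ref[ps]
  inside <- ref[ps] & dp > 0 # strictly interior to the reference
  ds <- mean(ifelse(inside, -dp, dp))
  du <- mean(dp)
  hd <- max(max(dp), max(d_to_pred[rs]))
  list(ds = ds, du = du, hd = hd)
}

#' Per-instance segmentation metrics
#'
#' Computes Dice and the surface-distance metrics for every matched
#' predicted/reference instance pair.
#'
#' @param pred,ref instance [labelmap()]s on the same grid.
#' @return A tibble with one row per matched pair: `pred_label`,
#'   `ref_label`, `dice`, `ds`, `du`, `hd`.
#' @export
instance_metrics <- function(pred, ref) {
  rep_ <- match_instances(pred, ref)
  pairs <- rep_$pairs
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pm <- pred$values == pairs$pred_label[i]
    rm <- ref$values == pairs$ref_label[i]
    sd_ <- surface_distances(pm, rm, pred$spacing)
    tibble::tibble(pred_label = pairs$pred_label[i],
                   ref_label = pairs$ref_label[i],
                   dice = dice(pm, rm), ds = sd_$ds, du = sd_$du,
                   hd = sd_$hd)
  })
  do.call(rbind, rows)
}

#' Match predicted to reference instances by maximum overlap
#'
#' Greedy one-to-one assignment by descending overlap voxel count: the
#' pair with the largest overlap is matched first, and each instance is
#' used at most once. Matched pairs (nonzero overlap) are true
#' positives; unmatched predicted instances are false positives and
#' unmatched reference instances false negatives.
#'
#' @param pred,ref instance [labelmap()]s on the same grid.
#' @return A `vertseg_match_report`: list with `pairs` (tibble
#'   `pred_label`, `ref_label`, `overlap`), `tp`, `fp`, `fn`, `f1`.
#' @export
match_instances <- function(pred, ref) {
  if (!identical(dim(pred$values), dim(ref$values)))
    stop("label maps are on different grids")
  p <- as.vector(pred$values); r <- as.vector(ref$values)
  both <- p > 0L & r > 0L
  pl <- sort(setdiff(unique(p), 0L)); rl <- sort(setdiff(unique(r), 0L))
  ov <- if (any(both)) {
    tab <- table(pred = p[both], ref = r[both])
    as.data.frame(tab, stringsAsFactors = FALSE)
  } else data.frame(pred = character(0), ref = character(0), Freq = integer(0))
  ov <- ov[ov$Freq > 0, , drop = FALSE]
  ov <- ov[order(-ov$Freq, as.integer(ov$pred), as.integer(ov$ref)), ,
           drop = FALSE]
  used_p <- integer(0); used_r <- integer(0)
  pairs <- list()
  for (i in seq_len(nrow(ov))) {
    pi <- as.integer(ov$pred[i]); ri <- as.integer(ov$ref[i])
    if (pi %in% used_p || ri %in% used_r) next
    pairs[[length(pairs) + 1L]] <-
      tibble::tibble(pred_label = pi, ref_label = ri, overlap = ov$Freq[i])
    used_p <- c(used_p, pi); used_r <- c(used_r, ri)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
  else tibble::tibble(pred_label = integer(0), ref_label = integer(0),
                      overlap = integer(0))
  tp <- nrow(pairs)
  fp <- length(pl) - tp
  fn <- length(rl) - tp
  structure(list(pairs = pairs, tp = tp, fp = fp, fn = fn,
                 f1 = f1_score(tp, fp, fn)),
            class = "vertseg_match_report")
}

#' F1 detection score from true/false positive and negative counts
#'
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @param tp,fp,fn non-negative counts.
#' @return Scalar in \[0, 1\] (`NaN` when all counts are zero).
#' @export
f1_score <- function(tp, fp, fn) {
  2 * tp / (2 * tp + fp + fn)
}

#' @export
print.vertseg_match_report <- function(x, ...) {
  cat(sprintf("<match report> TP %d, FP %d, FN %d, F1 %.3f\n",
              x$tp, x$fp, x$fn, x$f1))
  invisible(x)
}

#' Summarize per-instance metric rows
#'
#' @param rows a tibble of metric rows, e.g. from [instance_metrics()];
#'   all numeric columns except label columns are summarized.
#' @return A tibble with columns `metric`, `mean`, `sd`, `median`.
#' @export
summarize_metrics <- function(rows) {
  if (NROW(rows) < 1) stop("no metric rows to summarize")
  num <- rows[vapply(rows, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("pred_label", "ref_label"))]
  tibble::tibble(
    metric = names(num),
    mean = unname(vapply(num, mean, numeric(1))),
    sd = unname(vapply(num, function(x)
      if (length(x) > 1) stats::sd(x) else 0, numeric(1))),
    median = unname(vapply(num, stats::median, numeric(1))))
}
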