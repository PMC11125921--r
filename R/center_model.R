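#' Gaussian inter-vertebral distance model
#'
#' The prior that powers vertebra-count selection: one Gaussian per
#' neighbouring-pair index for the z-projected distance between
#' consecutive vertebra centers (index 1 = the lowest pair, counting up;
#' 17 pairs cover a full lumbar + thoracic stack), plus a single Gaussian
#' for the difference between consecutive distances, fitted on all pooled
#' gap differences.
#'
#' @param pair_mu,pair_sigma numeric vectors (one entry per pair index)
#'   of means and standard deviations (mm).
#' @param diff_mu,diff_sigma mean and sd (mm) of consecutive gap
#'   differences.
#' @param sigma_floor lower bound applied to all standard deviations
#'   (default 0.5 mm) to keep densities finite on degenerate fits.
#' @return A `vertseg_distance_model`.
#' @export
distance_model <- function(pair_mu, pair_sigma, diff_mu, diff_sigma,
                           sigma_floor = 0.5) {
  if (length(pair_mu) != length(pair_sigma))
    stop("pair_mu and pair_sigma lengths differ")
  structure(list(pair_mu = as.numeric(pair_mu),
                 pair_sigma = pmax(as.numeric(pair_sigma), sigma_floor),
                 diff_mu = as.numeric(diff_mu),
                 diff_sigma = max(as.numeric(diff_sigma), sigma_floor),
                 sigma_floor = sigma_floor),
            class = "vertseg_distance_model")
}

#' @export
print.vertseg_distance_model <- function(x, ...) {
  cat(sprintf("<distance model> %d pair gaussians, diff N(%.2f, %.2f)\n",
              length(x$pair_mu), x$diff_mu, x$diff_sigma))
  invisible(x)
}

#' Fit the distance model by maximum likelihood
#'
#' For each pair index i (counting from the bottom), the z-gaps between
#' the i-th and (i+1)-th centers of every training scan are collected and
#' a Gaussian is fitted by MLE (sample mean, biased standard deviation).
#' The difference Gaussian is fitted to all consecutive gap differences
#' pooled across scans and indices.
#'
#' @param training_center_lists list of per-scan center sets: each element
#'   is a numeric matrix (k x 3) of body centers in mm (z, y, x), ordered
#'   bottom to top, or a numeric vector of z-coordinates.
#' @param n_pairs number of pair Gaussians to fit (default 17). Every
#'   fitted index must be supported by at least 2 training scans.
#' @param sigma_floor lower bound on fitted standard deviations (mm).
#' @return A [distance_model()].
#' @export
fit_distance_model <- function(training_center_lists, n_pairs = 17,
                               sigma_floor = 0.5) {
  gaps_by_index <- vector("list", n_pairs)
  diffs <- numeric(0)
  for (cl in training_center_lists) {
    z <- if (is.matrix(cl)) cl[, 1] else as.numeric(cl)
    z <- sort(z)
    g <- diff(z)
    for (i in seq_along(g))
      if (i <= n_pairs) gaps_by_index[[i]] <- c(gaps_by_index[[i]], g[i])
    if (length(g) >= 2) diffs <- c(diffs, diff(g))
  }
  ns <- vapply(gaps_by_index, length, integer(1))
  if (any(ns < 2))
    stop("pair index ", paste(which(ns < 2), collapse = ", "),
         " has fewer than 2 training samples")
  mle_sd <- function(x) sqrt(mean((x - mean(x))^2))
  distance_model(
    pair_mu = vapply(gaps_by_index, mean, numeric(1)),
    pair_sigma = vapply(gaps_by_index, mle_sd, numeric(1)),
    diff_mu = mean(diffs),
    diff_sigma = if (length(diffs) >= 2) mle_sd(diffs) else 0,
    sigma_floor = sigma_floor)
}

#' Clustering score CS(k) of a candidate center set
#'
#' For every window of three consecutive centers (sorted by z; ties broken
#' by y then x) with gaps \eqn{D_i} and \eqn{D_{i+1}}, the product of the
#' two pair-Gaussian densities and the difference-Gaussian density at
#' \eqn{D_{i+1}-D_i} is formed; the score is the minimum product over all
#' windows - the worst-matching local configuration. Gap indices beyond
#' the fitted pairs reuse the last pair Gaussian.
#'
#' @param centers numeric matrix (k x 3, mm) or vector of z-coordinates;
#'   k must be at least 3.
#' @param model a [distance_model()].
#' @param normalized if `FALSE`, each Gaussian is evaluated relative to
#'   its peak instead of as a normalized density (sensitivity variant).
#' @return The scalar score.
#' @export
clustering_score <- function(centers, model, normalized = TRUE) {
  z <- sort_centers_z(centers)
  k <- length(z)
  if (k < 3) stop("clustering score undefined for fewer than 3 centers")
  gaps <- diff(z)
  m <- length(model$pair_mu)
  gi <- pmin(seq_along(gaps), m)
  dens <- stats::dnorm(gaps, model$pair_mu[gi], model$pair_sigma[gi])
  ddens <- stats::dnorm(diff(gaps), model$diff_mu, model$diff_sigma)
  if (!normalized) {
    dens <- dens / stats::dnorm(0, 0, model$pair_sigma[gi])
    ddens <- ddens / stats::dnorm(0, 0, model$diff_sigma)
  }
  min(dens[-length(dens)] * dens[-1] * ddens)
}

# z-sorted center z-coordinates with (z, y, x) lexicographic tie-break
sort_centers_z <- function(centers) {
  if (is.matrix(centers))
    centers[order(centers[, 1], centers[, 2], centers[, 3]), 1]
  else sort(as.numeric(centers))
}

#' Weighted k-means clustering of center votes
#'
#' Lloyd iterations on confidence-weighted votes, with weighted
#' probabilistic farthest-point seeding (k-means++ style, weight times
#' squared distance) under a fixed seed. An emptied cluster is re-seeded
#' at the vote with the largest weighted squared distance to its current
#' center. `n_start` independent seeded restarts are run and the solution
#' with the smallest weighted within-cluster sum of squares is kept,
#' guarding against the local optima Lloyd iterations are prone to.
#' Scaling all weights by a positive constant does not change the result.
#'
#' @param votes tibble/data.frame with columns `z`, `y`, `x`, `weight`
#'   (weights in (0, 1]), e.g. from [generate_center_votes()].
#' @param k number of clusters; at most the number of distinct vote
#'   positions.
#' @param seed integer seed for the initialization.
#' @param max_iter Lloyd iteration cap.
#' @param n_start number of seeded restarts (default 8).
#' @return Numeric matrix (k x 3) of cluster centers (mm), sorted by z.
#' @export
weighted_kmeans <- function(votes, k, seed = 1L, max_iter = 100,
                            n_start = 8) {
  best <- NULL
  best_wss <- Inf
  for (s in seq_len(n_start)) {
    run <- weighted_kmeans_once(votes, k, seed = seed + (s - 1L) * 1009L,
                                max_iter = max_iter)
    if (run$wss < best_wss) {
      best_wss <- run$wss
      best <- run$centers
    }
  }
  best
}

weighted_kmeans_once <- function(votes, k, seed, max_iter = 100) {
  pts <- as.matrix(votes[, c("z", "y", "x")])
  w <- votes$weight
  if (any(w <= 0)) stop("vote weights must be positive")
  if (nrow(unique(pts)) < k) stop("fewer distinct votes than clusters")
  n <- nrow(pts)
  with_rng(seed, {
    centers <- matrix(NA_real_, k, 3)
    centers[1, ] <- pts[sample.int(n, 1, prob = w), ]
    if (k > 1) for (j in 2:k) {
      d2 <- apply(centers[seq_len(j - 1), , drop = FALSE], 1, function(cc)
        colSums((t(pts) - cc)^2))
      d2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
      p <- w * d2
      if (all(p == 0)) p <- rep(1, n)
      centers[j, ] <- pts[sample.int(n, 1, prob = p), ]
    }
    assign_prev <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      d2 <- vapply(seq_len(k), function(j)
        colSums((t(pts) - centers[j, ])^2), numeric(n))
      a <- max.col(-d2, ties.method = "first")
      empty <- which(tabulate(a, k) == 0L)
      if (length(empty)) {
        # re-seed each emptied cluster at a distinct vote, by decreasing
        # weighted squared distance to its current center
        ord <- order(-(w * d2[cbind(seq_len(n), a)]))
        taken <- integer(0)
        for (j in empty) {
          pick <- ord[!(ord %in% taken)][1]
          a[pick] <- j
          taken <- c(taken, pick)
        }
      }
      for (j in seq_len(k)) {
        sel <- a == j
        if (any(sel))
          centers[j, ] <- colSums(pts[sel, , drop = FALSE] * w[sel]) /
            sum(w[sel])
      }
      if (all(a == assign_prev)) break
      assign_prev <- a
    }
    d2 <- vapply(seq_len(k), function(j)
      colSums((t(pts) - centers[j, ])^2), numeric(n))
    a <- max.col(-d2, ties.method = "first")
    list(centers = centers[order(centers[, 1], centers[, 2],
                                 centers[, 3]), , drop = FALSE],
         wss = sum(w * d2[cbind(seq_len(n), a)]))
  })
}

#' Select the vertebra count by maximizing the clustering score
#'
#' Runs weighted k-means for every candidate k and evaluates CS(k) on the
#' z-sorted centers; the k with the maximal score wins. Votes inside an
#' optional exclusion region (e.g. the segmented pelvis) are removed
#' beforehand. Candidates with more clusters than distinct votes, or
#' whose gap count exceeds what the model plus last-Gaussian reuse can
#' weight, score `-Inf`.
#'
#' @inheritParams weighted_kmeans
#' @param model a [distance_model()].
#' @param k_range candidate range for k (default 3 to 19).
#' @param exclusion optional region: a logical function of an (n x 3) mm
#'   position matrix returning `TRUE` for votes to drop, or a [volume()]
#'   / [labelmap()] whose nonzero voxels mark the excluded region.
#' @return A `vertseg_cluster_result`: list with `kopti`, `centers`
#'   (kopti x 3, z-sorted), `score_by_k` (named vector, diagnostics) and
#'   `votes_used`.
#' @export
select_k <- function(votes, model, k_range = c(3, 19), exclusion = NULL,
                     seed = 1L) {
  if (!is.null(exclusion)) {
    pos <- as.matrix(votes[, c("z", "y", "x")])
    drop <- if (is.function(exclusion)) exclusion(pos)
    else {
      idx <- round(mm_to_voxel(pos, exclusion))
      d <- dim(exclusion$values)
      inb <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
        idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
      out <- rep(FALSE, nrow(idx))
      out[inb] <- exclusion$values[idx[inb, , drop = FALSE]] != 0
      out
    }
    votes <- votes[!drop, , drop = FALSE]
  }
  if (nrow(votes) < 3) stop("fewer than 3 votes after exclusion")
  ks <- seq.int(k_range[1], k_range[2])
  if (min(ks) < 3) stop("k must start at 3 or above")
  scores <- stats::setNames(rep(-Inf, length(ks)), ks)
  centers_by_k <- vector("list", length(ks))
  n_distinct <- nrow(unique(as.matrix(votes[, c("z", "y", "x")])))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k > n_distinct) next
    cen <- weighted_kmeans(votes, k, seed = seed)
    centers_by_k[[i]] <- cen
    scores[i] <- clustering_score(cen, model)
  }
  if (all(!is.finite(scores))) stop("no candidate k could be scored")
  best <- which.max(scores)
  structure(list(kopti = ks[best], centers = centers_by_k[[best]],
                 score_by_k = scores, votes_used = nrow(votes)),
            class = "vertseg_cluster_result")
}

#' @export
print.vertseg_cluster_result <- function(x, ...) {
  cat(sprintf("<cluster result> kopti = %d (from %d votes)\n",
              x$kopti, x$votes_used))
  invisible(x)
}

#' Diagnostic plot of the clustering score versus k
#'
#' @param x a [select_k()] result.
#' @param ... passed to [plot()].
#' @export
plot.vertseg_cluster_result <- function(x, ...) {
  ks <- as.integer(names(x$score_by_k))
  s <- x$score_by_k
  fin <- is.finite(s)
  plot(ks[fin], log10(pmax(s[fin], .Machine$double.xmin)), type = "b",
       xlab = "k", ylab = "log10 CS(k)", ...)
  graphics::abline(v = x$kopti, lty = 2)
  invisible(x)
}

#' Serialize a distance model to JSON
#'
#' @param model a [distance_model()].
#' @param path output JSON path.
#' @export
write_distance_model <- function(model, path) {
  jsonlite::write_json(
    list(pairs = cbind(model$pair_mu, model$pair_sigma),
         diff = c(model$diff_mu, model$diff_sigma),
         sigma_floor = model$sigma_floor),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distance_model
#' @export
read_distance_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  distance_model(j$pairs[, 1], j$pairs[, 2], j$diff[1], j$diff[2],
                 sigma_floor = j$sigma_floor)
}
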