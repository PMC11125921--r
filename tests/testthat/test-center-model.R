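# a well-behaved synthetic distance model: slowly shrinking gaps toward
# the upper thoracic levels, as in real spines
synthetic_model <- function(mu1 = 30, step = -0.5, sigma = 2, dsig = 2) {
  distance_model(pair_mu = mu1 + step * (0:16), pair_sigma = rep(sigma, 17),
                 diff_mu = step, diff_sigma = dsig)
}

# center stacks spaced at the model's means
model_centers <- function(model, k, z0 = 50) {
  z <- z0 + c(0, cumsum(model$pair_mu[seq_len(k - 1)]))
  cbind(z, 20, 20)
}

test_that("MLE fitting recovers mean and biased sd, with the sigma floor", {
  lists <- lapply(1:5, function(i) cbind(c(0, 30, 60, 90), 0, 0))
  dm <- fit_distance_model(lists, n_pairs = 3)
  expect_equal(dm$pair_mu, rep(30, 3))
  expect_equal(dm$pair_sigma, rep(0.5, 3)) # degenerate fits floored
  expect_equal(dm$diff_mu, 0)
})

test_that("fitted means concentrate at the closed-form standard error", {
  n <- 500
  withr::with_seed(17, {
    lists <- lapply(seq_len(n), function(i) {
      gaps <- stats::rnorm(3, 30, 2)
      cbind(cumsum(c(0, gaps)), 0, 0)
    })
  })
  dm <- fit_distance_model(lists, n_pairs = 3)
  # standard error of the mean is 2/sqrt(500) ~ 0.09; use a 3.3 sigma band
  expect_true(all(abs(dm$pair_mu - 30) < 0.3))
  expect_true(all(abs(dm$pair_sigma - 2) < 0.3))
})

test_that("fitting fails loudly when a pair index lacks support", {
  lists <- list(cbind(c(0, 30, 60), 0, 0), cbind(c(0, 30), 0, 0))
  expect_error(fit_distance_model(lists, n_pairs = 2), "2")
})

test_that("the clustering score peaks at the model's modes", {
  dm <- synthetic_model()
  k <- 3
  ctr <- model_centers(dm, k)
  # gaps at the modes and gap difference at its mode: the peak product
  peak <- stats::dnorm(dm$pair_mu[1], dm$pair_mu[1], dm$pair_sigma[1]) *
    stats::dnorm(dm$pair_mu[2], dm$pair_mu[2], dm$pair_sigma[2]) *
    stats::dnorm(dm$diff_mu, dm$diff_mu, dm$diff_sigma)
  expect_equal(clustering_score(ctr, dm), peak, tolerance = 1e-12)
  # perturbing one gap away from its mode strictly decreases the score
  for (delta in c(-4, -2, -1, 1, 2, 4)) {
    pert <- ctr; pert[3, 1] <- pert[3, 1] + delta
    expect_lt(clustering_score(pert, dm), clustering_score(ctr, dm))
  }
})

test_that("CS(k) is the minimum over exhaustively enumerated windows", {
  dm <- synthetic_model()
  withr::with_seed(23, {
    z <- 50 + cumsum(c(0, stats::rnorm(4, 29, 3)))
  })
  ctr <- cbind(z, 0, 0)
  gaps <- diff(sort(z))
  oracle <- min(vapply(1:3, function(i)
    stats::dnorm(gaps[i], dm$pair_mu[i], dm$pair_sigma[i]) *
      stats::dnorm(gaps[i + 1], dm$pair_mu[i + 1], dm$pair_sigma[i + 1]) *
      stats::dnorm(gaps[i + 1] - gaps[i], dm$diff_mu, dm$diff_sigma),
    numeric(1)))
  expect_equal(clustering_score(ctr, dm), oracle, tolerance = 1e-12)
})

test_that("the clustering score ignores input ordering", {
  dm <- synthetic_model()
  ctr <- model_centers(dm, 5)
  withr::with_seed(29, shuf <- ctr[sample(5), ])
  expect_equal(clustering_score(shuf, dm), clustering_score(ctr, dm))
  expect_error(clustering_score(ctr[1:2, ], dm), "fewer than 3")
})

test_that("gap indices beyond the fitted pairs reuse the last Gaussian", {
  dm <- synthetic_model()
  ctr18 <- model_centers(dm, 18)
  ctr19 <- rbind(ctr18, c(ctr18[18, 1] + dm$pair_mu[17], 20, 20))
  expect_true(is.finite(clustering_score(ctr19, dm)))
})

test_that("weighted k-means with k = 1 is the closed-form weighted mean", {
  withr::with_seed(31, {
    v <- tibble::tibble(z = stats::rnorm(40, 50, 5),
                        y = stats::rnorm(40, 20, 2),
                        x = stats::rnorm(40, 20, 2),
                        weight = stats::runif(40, 0.1, 1))
  })
  got <- weighted_kmeans(v, 1, seed = 3)
  oracle <- colSums(as.matrix(v[, c("z", "y", "x")]) * v$weight) /
    sum(v$weight)
  expect_equal(unname(got[1, ]), unname(oracle), tolerance = 1e-9)
})

test_that("scaling all weights leaves the clustering unchanged", {
  dm <- synthetic_model()
  votes <- generate_center_votes(model_centers(dm, 4), 15, 2, seed = 5)
  a <- weighted_kmeans(votes, 4, seed = 9)
  votes2 <- votes; votes2$weight <- votes2$weight * 0.37
  b <- weighted_kmeans(votes2, 4, seed = 9)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("equal weights reproduce a Lloyd fixed point of stats::kmeans", {
  withr::with_seed(41, {
    pts <- rbind(matrix(stats::rnorm(60, 0, 1), ncol = 3),
                 matrix(stats::rnorm(60, 12, 1), ncol = 3),
                 matrix(stats::rnorm(60, 24, 1), ncol = 3))
  })
  v <- tibble::tibble(z = pts[, 1], y = pts[, 2], x = pts[, 3], weight = 1)
  ours <- weighted_kmeans(v, 3, seed = 2)
  # our converged centers must be a fixed point of the unweighted Lloyd
  # iteration as implemented independently by stats::kmeans
  km <- stats::kmeans(pts, centers = ours, iter.max = 50,
                      algorithm = "Lloyd")
  ref <- km$centers[order(km$centers[, 1]), , drop = FALSE]
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("well-separated clusters are recovered at vote-noise accuracy", {
  dm <- synthetic_model()
  true <- model_centers(dm, 4)
  votes <- generate_center_votes(true, 30, 1.5, seed = 7)
  got <- weighted_kmeans(votes, 4, seed = 11)
  # oracle: per-cluster weighted means from the known assignments
  oracle <- t(vapply(1:4, function(k) {
    sub <- votes[votes$true_cluster == k, ]
    colSums(as.matrix(sub[, c("z", "y", "x")]) * sub$weight) /
      sum(sub$weight)
  }, numeric(3)))
  expect_equal(unname(got), unname(oracle), tolerance = 0.5)
  expect_error(weighted_kmeans(votes[1:3, ], 4), "fewer distinct votes")
})

test_that("select_k finds the count of zero-noise point clusters exactly", {
  dm <- synthetic_model()
  true <- model_centers(dm, 3)
  votes <- generate_center_votes(true, 12, 0, seed = 3)
  res <- select_k(votes, dm, k_range = c(3, 19), seed = 5)
  expect_equal(res$kopti, 3)
  expect_equal(unname(res$centers), unname(true), tolerance = 1e-9)
  expect_true(all(as.integer(names(res$score_by_k)) %in% 3:19))
})

test_that("votes inside the exclusion region do not affect the result", {
  dm <- synthetic_model()
  true <- model_centers(dm, 5, z0 = 60)
  votes <- generate_center_votes(true, 20, 1, seed = 13)
  base <- select_k(votes, dm, exclusion = function(p) p[, 1] < 40, seed = 2)
  # pollute with pelvis-region votes below z = 40
  junk <- tibble::tibble(z = stats::runif(30, 10, 35), y = 20, x = 20,
                         weight = 1, true_cluster = NA_integer_)
  polluted <- rbind(votes, junk)
  got <- select_k(polluted, dm, exclusion = function(p) p[, 1] < 40,
                  seed = 2)
  expect_equal(got$kopti, base$kopti)
  expect_equal(got$centers, base$centers, tolerance = 1e-12)
  expect_error(select_k(junk, dm, exclusion = function(p) p[, 1] < 40),
               "fewer than 3")
})

test_that("an exclusion label map works like an exclusion function", {
  dm <- synthetic_model()
  true <- model_centers(dm, 4, z0 = 40)
  votes <- generate_center_votes(true, 15, 1, seed = 19)
  mask <- array(0L, c(100, 40, 40))
  mask[1:10, , ] <- 1L # excluded bottom slab (z < 20 mm at 2 mm spacing)
  ex <- labelmap(mask, spacing = c(2, 1, 1))
  junk <- tibble::tibble(z = stats::runif(20, 0, 18), y = 20, x = 20,
                         weight = 1, true_cluster = NA_integer_)
  got <- select_k(rbind(votes, junk), dm, exclusion = ex, seed = 4)
  base <- select_k(votes, dm, exclusion = ex, seed = 4)
  expect_equal(got$kopti, base$kopti)
  expect_equal(got$centers, base$centers, tolerance = 1e-12)
})

test_that("the selected k never leaves the allowed range", {
  dm <- synthetic_model()
  for (k in c(3, 6, 10)) {
    votes <- generate_center_votes(model_centers(dm, k), 10, 1, seed = k)
    res <- select_k(votes, dm, seed = k)
    expect_gte(res$kopti, 3)
    expect_lte(res$kopti, 19)
  }
})

test_that("distance models survive the JSON round trip", {
  dm <- synthetic_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_distance_model(dm, path)
  dm2 <- read_distance_model(path)
  expect_equal(dm2$pair_mu, dm$pair_mu, tolerance = 1e-12)
  expect_equal(dm2$pair_sigma, dm$pair_sigma, tolerance = 1e-12)
  expect_equal(dm2$diff_mu, dm$diff_mu, tolerance = 1e-12)
  expect_equal(dm2$diff_sigma, dm$diff_sigma, tolerance = 1e-12)
})
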