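test_that("patch lattice matches the closed-form count and clamping rules", {
  g <- build_patch_grid(c(64, 96, 96), c(32, 48, 48), 0.5)
  # oracle: floor((L - P) / S) + 1 positions per axis, plus the clamped
  # last origin when the stride does not land on it exactly
  n_axis <- function(L, P, S) length(unique(c(seq(1, L - P + 1, S), L - P + 1)))
  expect_equal(nrow(g$origins),
               n_axis(64, 32, 16) * n_axis(96, 48, 24) * n_axis(96, 48, 24))
  expect_equal(nrow(g$origins), 27)
  g1 <- build_patch_grid(c(32, 48, 48), c(32, 48, 48), 0.5)
  expect_equal(nrow(g1$origins), 1)
  expect_equal(unname(g1$origins[1, ]), c(1, 1, 1))
  expect_warning(build_patch_grid(c(16, 20, 20), c(32, 48, 48), 0.5),
                 "clamped")
  expect_error(build_patch_grid(c(30, 30, 30), c(7, 7, 7), 0.5), "stride")
})

test_that("every VOI voxel is covered by at least one patch", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      voi <- c(sample(32:70, 1), sample(48:100, 1), sample(48:100, 1))
      g <- build_patch_grid(voi, c(32, 48, 48), 0.5)
      cov <- array(0L, voi)
      for (i in seq_len(nrow(g$origins))) {
        o <- g$origins[i, ]; h <- o + g$patch_size - 1
        cov[o[1]:h[1], o[2]:h[2], o[3]:h[3]] <-
          cov[o[1]:h[1], o[2]:h[2], o[3]:h[3]] + 1L
      }
      expect_true(all(cov >= 1L))
    }
  })
})

# a stack of axis-aligned boxes is enough to exercise every visibility rule
box_stack <- function(z_ranges, y_ranges = NULL, dims = c(40, 60, 30)) {
  vals <- array(0L, dims)
  for (i in seq_along(z_ranges)) {
    zr <- z_ranges[[i]]
    yr <- if (is.null(y_ranges)) c(10, 29) else y_ranges[[i]]
    vals[zr[1]:zr[2], yr[1]:yr[2], 6:25] <- i
  }
  labelmap(vals, spacing = c(1, 1, 1))
}

test_that("the published three-vertebra confidence example reproduces", {
  # three consecutive vertebrae of 4000 voxels each (10 x 20 x 20 boxes)
  # with 600, 1000 and 400 voxels inside the patch
  lm <- box_stack(list(c(2, 11), c(14, 23), c(26, 35)),
                  list(c(38, 57), c(36, 55), c(39, 58)),
                  dims = c(40, 70, 30))
  expect_equal(unname(tabulate(lm$values)), rep(4000L, 3))
  patch_origin <- c(1, 1, 1); patch_size <- c(40, 40, 30)
  inside <- vapply(1:3, function(l)
    sum(extract_patch(lm$values, patch_origin, patch_size) == l), numeric(1))
  expect_equal(inside, c(600, 1000, 400))
  ctrs <- instance_body_centers(lm)
  tgt <- localization_target(patch_origin, patch_size, lm, ctrs)
  expect_equal(unname(tgt$confidences["mid"]), 0.25)
  expect_equal(unname(tgt$confidences["bottom"]), 0.15)
  expect_equal(unname(tgt$confidences["top"]), 0.10)
  expect_equal(unname(tgt$labels["mid"]), 2)
})

test_that("a single fully contained vertebra is the mid with confidence 1", {
  lm <- box_stack(list(c(10, 19)))
  ctrs <- instance_body_centers(lm)
  tgt <- localization_target(c(1, 1, 1), c(40, 60, 30), lm, ctrs)
  expect_equal(unname(tgt$confidences["mid"]), 1)
  expect_equal(unname(tgt$confidences[c("top", "bottom")]), c(0, 0))
  expect_equal(unname(tgt$labels["mid"]), 1)
  v12 <- as.numeric(tgt)
  expect_length(v12, 12)
  expect_equal(v12[10:12], c(0, 1, 0)) # (conf top, conf mid, conf bottom)
})

test_that("with two visible vertebrae the lower is the mid-center", {
  lm <- box_stack(list(c(5, 14), c(20, 29)))
  ctrs <- instance_body_centers(lm)
  tgt <- localization_target(c(1, 1, 1), c(40, 60, 30), lm, ctrs)
  expect_equal(unname(tgt$labels["mid"]), 1)
  expect_equal(unname(tgt$labels["top"]), 2)
  expect_gt(tgt$confidences["top"], 0)
  # absent bottom neighbour: confidence 0 and mirrored position
  expect_equal(unname(tgt$confidences["bottom"]), 0)
  mirrored <- 2 * (ctrs[1, ] + tgt$patch_center * 0) - ctrs[2, ]
  expect_equal(unname(tgt$offsets["bottom", ] + tgt$patch_center),
               unname(mirrored))
})

test_that("with more than three visible the lowest confidences drop first", {
  lm <- box_stack(list(c(1, 10), c(12, 21), c(23, 32), c(34, 38)))
  # patch covering everything: confidences 1, 1, 1, 0.5 -> drop label 4
  ctrs <- instance_body_centers(lm)
  tgt <- localization_target(c(1, 1, 1), c(38, 60, 30), lm, ctrs)
  expect_equal(unname(tgt$labels["mid"]), 2)
  # equal-lowest tie: the topmost of the tied is dropped
  lm2 <- box_stack(list(c(1, 10), c(12, 21), c(23, 32), c(34, 38)))
  vals <- lm2$values
  vals[36:38, , ] <- 0L # shrink label 4 so 1..3 are full, 4 partial
  lm2 <- labelmap(vals, spacing = c(1, 1, 1))
  ctrs2 <- instance_body_centers(lm2)
  tgt2 <- localization_target(c(1, 1, 1), c(38, 60, 30), lm2, ctrs2)
  expect_equal(unname(tgt2$labels["mid"]), 2)
})

test_that("localization targets are translation equivariant", {
  lm <- box_stack(list(c(5, 14), c(17, 26), c(29, 38)))
  ctrs <- instance_body_centers(lm)
  t1 <- localization_target(c(1, 6, 1), c(30, 40, 30), lm, ctrs)
  # shift patch and labels together by (2, 4, 0)
  shifted <- array(0L, dim(lm$values))
  shifted[3:40, 5:60, ] <- lm$values[1:38, 1:56, ]
  lm2 <- labelmap(shifted, spacing = c(1, 1, 1))
  ctrs2 <- instance_body_centers(lm2)
  t2 <- localization_target(c(3, 10, 1), c(30, 40, 30), lm2, ctrs2)
  expect_equal(t2$offsets, t1$offsets, tolerance = 1e-9)
  expect_equal(t2$confidences, t1$confidences, tolerance = 1e-12)
})

test_that("a patch without instance voxels is rejected as a target", {
  lm <- box_stack(list(c(30, 39)))
  expect_error(localization_target(c(1, 1, 1), c(10, 10, 10), lm,
                                   instance_body_centers(lm)),
               "no instance voxels")
})

test_that("interior confidences accumulate to the overlap multiplicity", {
  # with 50% overlap every voxel of the VOI core lies in exactly 8
  # patches, so the per-patch volume fractions of a core vertebra sum to
  # exactly 8
  voi <- c(64, 96, 96)
  grid <- build_patch_grid(voi, c(32, 48, 48), 0.5)
  vals <- array(0L, voi)
  vals[20:45, 30:60, 30:60] <- 1L  # fully inside the doubly covered core
  lm <- labelmap(vals)
  total <- sum(vals == 1L)
  acc <- 0
  for (i in seq_len(nrow(grid$origins))) {
    o <- grid$origins[i, ]
    acc <- acc + sum(extract_patch(vals, o, grid$patch_size) == 1L) / total
  }
  expect_equal(acc, 8, tolerance = 1e-12)
})

test_that("training batches respect the vertebra quota and the seed", {
  ph <- tiny_phantom(n = 4, seed = 52)
  grid <- build_patch_grid(dim(ph$labels$values), c(32, 48, 48), 0.5)
  b <- sample_training_batch(grid, ph$labels, 32, 0.5, seed = 5)
  expect_equal(nrow(b), 32)
  n_fg <- sum(vapply(seq_len(32), function(i)
    any(extract_patch(ph$labels$values, b[i, ], grid$patch_size) != 0L),
    logical(1)))
  expect_gte(n_fg, 16)
  b_all <- sample_training_batch(grid, ph$labels, 16, 1, seed = 6)
  n_all <- sum(vapply(seq_len(16), function(i)
    any(extract_patch(ph$labels$values, b_all[i, ], grid$patch_size) != 0L),
    logical(1)))
  expect_equal(n_all, 16)
  expect_identical(sample_training_batch(grid, ph$labels, 8, 0.5, seed = 9),
                   sample_training_batch(grid, ph$labels, 8, 0.5, seed = 9))
  expect_error(sample_training_batch(grid, ph$labels, 1), "batch_size")
})

test_that("stitching averages overlapping probabilities then takes argmax", {
  # two overlapping patches with conflicting probabilities, against an
  # explicit sum/count accumulation oracle
  voi <- c(4, 4, 6)
  g <- build_patch_grid(voi, c(4, 4, 4), 0.5)
  expect_equal(nrow(g$origins), 2)
  withr::with_seed(31, {
    p1 <- array(stats::runif(4 * 4 * 4 * 3), c(4, 4, 4, 3))
    p2 <- array(stats::runif(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  })
  got <- stitch_predictions(list(p1, p2), g, spacing = c(1, 1, 1))
  acc <- array(0, c(voi, 3)); cnt <- array(0, voi)
  for (pp in list(list(p1, 1), list(p2, 3))) {
    xr <- pp[[2]]:(pp[[2]] + 3)
    acc[, , xr, ] <- acc[, , xr, , drop = FALSE] + pp[[1]]
    cnt[, , xr] <- cnt[, , xr] + 1
  }
  oracle <- array(0L, voi)
  for (i in 1:4) for (j in 1:4) for (k in 1:6)
    oracle[i, j, k] <- which.max(acc[i, j, k, ] / cnt[i, j, k]) - 1L
  expect_identical(got$values, oracle)
})

test_that("stitching unanimous or empty predictions is exact", {
  voi <- c(4, 4, 6)
  g <- build_patch_grid(voi, c(4, 4, 4), 0.5)
  onehot_bg <- array(0, c(4, 4, 4, 3)); onehot_bg[, , , 1] <- 1
  empty <- stitch_predictions(list(onehot_bg, onehot_bg), g, c(1, 1, 1))
  expect_true(all(empty$values == 0L))
  expect_error(stitch_predictions(list(onehot_bg), g, c(1, 1, 1)),
               "one probability block")
})

test_that("mean vertebra volume averages instance sizes", {
  vals <- array(0L, c(10, 10, 10))
  vals[1:2, 1:5, 1:5] <- 1L  # 50 voxels
  vals[5:6, 1:5, 1:10] <- 2L # 100 voxels
  expect_equal(mean_vertebra_volume(labelmap(vals)), 75)
})
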