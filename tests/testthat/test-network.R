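# small configurations keep these tests fast; the architecture is the
# same at any width
tiny_cfg <- function(patch = c(8, 8, 8), seed = 2)
  model_config(tiers = 2, base_channels = 2, patch_size = patch,
               head_conv_channels = 2, head_fc = c(8, 8, 8), seed = seed)

test_that("both branches emit their contracted output shapes", {
  m <- build_model(tiny_cfg(c(16, 24, 24)))
  withr::with_seed(3, x <- array(stats::rnorm(16 * 24 * 24), c(16, 24, 24)))
  out <- predict_patch(m, x)
  expect_equal(dim(out$probs), c(16, 24, 24, 3))
  expect_true(all(abs(apply(out$probs, 1:3, sum) - 1) < 1e-9))
  expect_true(all(out$probs >= 0))
  expect_length(out$loc, 12)
  expect_true(all(out$loc[10:12] >= 0 & out$loc[10:12] <= 1))
  expect_error(predict_patch(m, array(0, c(8, 8, 8))), "wrong shape")
  expect_error(model_config(tiers = 3, patch_size = c(10, 12, 12)),
               "divisible")
})

test_that("model building and evaluation are deterministic", {
  a <- build_model(tiny_cfg(seed = 5))
  b <- build_model(tiny_cfg(seed = 5))
  expect_identical(a$params, b$params)
  c2 <- build_model(tiny_cfg(seed = 6))
  expect_false(identical(a$params, c2$params))
  withr::with_seed(4, x <- array(stats::rnorm(512), c(8, 8, 8)))
  p1 <- predict_patch(a, x)
  p2 <- predict_patch(a, x)
  expect_identical(p1, p2)
})

test_that("parameter count is independent of the input volume size", {
  n_par <- function(cfg) sum(lengths(rapply(build_model(cfg)$params,
                                            function(x) x, how = "unlist")))
  expect_equal(n_par(tiny_cfg(c(8, 8, 8))), n_par(tiny_cfg(c(8, 8, 8))))
  # the seg branch is fully convolutional: the same weights run on a
  # larger patch
  m <- build_model(tiny_cfg(c(8, 8, 8)))
  big <- vertseg:::seg_forward(m, array(0, c(16, 16, 16)))
  expect_equal(nrow(big$probs), 16^3)
})

test_that("the soft Dice loss attains its defining extremes", {
  n <- 60
  onehot <- vertseg:::onehot3(rep(c(0, 1, 2), each = n / 3))
  logits_match <- onehot * 40
  ls <- vertseg:::soft_dice_loss(logits_match, onehot)
  expect_lt(ls$loss, 1e-4)
  # disjoint prediction: every voxel assigned to a wrong class
  wrong <- onehot[, c(2, 3, 1)] * 40
  ls2 <- vertseg:::soft_dice_loss(wrong, onehot)
  expect_gt(ls2$loss, 0.999)
})

test_that("segmentation gradients match numerical differentiation", {
  m <- build_model(tiny_cfg())
  withr::with_seed(8, {
    x <- array(stats::rnorm(512), c(8, 8, 8))
    y <- array(sample(0:2, 512, TRUE), c(8, 8, 8))
  })
  oh <- vertseg:::onehot3(y)
  fwd <- vertseg:::seg_forward(m, x, train = TRUE)
  g <- vertseg:::seg_backward(m, fwd,
                              vertseg:::soft_dice_loss(fwd$logits, oh)$dlogits)
  loss_at <- function(mm) {
    f <- vertseg:::seg_forward(mm, x, train = TRUE)
    vertseg:::soft_dice_loss(f$logits, oh)$loss
  }
  checks <- list(
    list(get = function(mm) mm$params$seg$enc[[1]]$c1$W[7, 1],
         set = function(mm, v) { mm$params$seg$enc[[1]]$c1$W[7, 1] <- v; mm },
         grad = function(gg) gg$enc[[1]]$c1$W[7, 1]),
    list(get = function(mm) mm$params$seg$dec[[1]]$c2$gamma[2],
         set = function(mm, v) { mm$params$seg$dec[[1]]$c2$gamma[2] <- v; mm },
         grad = function(gg) gg$dec[[1]]$c2$gamma[2]),
    list(get = function(mm) mm$params$seg$out$b[3],
         set = function(mm, v) { mm$params$seg$out$b[3] <- v; mm },
         grad = function(gg) gg$out$b[3]))
  for (ck in checks) {
    eps <- 1e-5
    num <- (loss_at(ck$set(m, ck$get(m) + eps)) -
              loss_at(ck$set(m, ck$get(m) - eps))) / (2 * eps)
    expect_equal(ck$grad(g), num, tolerance = 1e-5)
  }
})

test_that("localization head gradients match numerical differentiation", {
  m <- build_model(tiny_cfg())
  withr::with_seed(9, {
    bns <- lapply(1:3, function(i) matrix(stats::rnorm(64 * 4), 64, 4))
    tgt <- matrix(stats::rnorm(36), 3, 12)
  })
  fwd <- vertseg:::head_forward(m, bns, train = TRUE)
  g <- vertseg:::head_backward(m, fwd, 2 * (fwd$out - tgt) / 36)
  loss_at <- function(mm)
    mean((vertseg:::head_forward(mm, bns, train = TRUE)$out - tgt)^2)
  eps <- 1e-5
  for (ck in list(
    list(get = function(mm) mm$params$loc$conv$W[2, 1],
         set = function(mm, v) { mm$params$loc$conv$W[2, 1] <- v; mm },
         grad = function(gg) gg$conv$W[2, 1]),
    list(get = function(mm) mm$params$loc$fc[[3]]$b[5],
         set = function(mm, v) { mm$params$loc$fc[[3]]$b[5] <- v; mm },
         grad = function(gg) gg$fc[[3]]$b[5]),
    list(get = function(mm) mm$params$loc$fc_out$W[4, 11],
         set = function(mm, v) { mm$params$loc$fc_out$W[4, 11] <- v; mm },
         grad = function(gg) gg$fc_out$W[4, 11]))) {
    num <- (loss_at(ck$set(m, ck$get(m) + eps)) -
              loss_at(ck$set(m, ck$get(m) - eps))) / (2 * eps)
    expect_equal(ck$grad(g), num, tolerance = 1e-4)
  }
})

test_that("the volume gate applies its threshold inclusively", {
  # >= 15% of the mean vertebra volume participates, below does not
  expect_true(vertseg:::loc_gate(150, 0.15, 1000))
  expect_true(vertseg:::loc_gate(151, 0.15, 1000))
  expect_false(vertseg:::loc_gate(149, 0.15, 1000))
  # raising the gate fraction never admits more patches
  fgs <- c(50, 120, 150, 300, 800)
  n_at <- function(f) sum(vertseg:::loc_gate(fgs, f, 1000))
  fracs <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(vapply(fracs, n_at, numeric(1))) <= 0))
})

test_that("a tiny network memorizes one labeled patch", {
  ph <- tiny_phantom(n = 4, seed = 1)
  st <- compute_norm_stats(ph$volume)
  vol <- clip_and_normalize(ph$volume, st)
  tlm <- encode_three_label(ph$labels)
  o <- c(20, 10, 20); sz <- c(16, 24, 24)
  x <- extract_patch(vol$values, o, sz)
  y <- extract_patch(tlm$values, o, sz)
  m <- build_model(model_config(tiers = 2, base_channels = 4,
                                patch_size = sz, seed = 3))
  tc <- train_config(batch_size = 1, seg_epochs = 150, seg_lr = 1e-2,
                     seed = 4)
  m <- train_segmentation(m, list(x = list(x), y = list(y)), tc)
  fwd <- vertseg:::seg_forward(m, x)
  cls <- max.col(fwd$probs, ties.method = "first") - 1L
  fg_dice <- dice(array(cls != 0L, sz), y != 0L)
  expect_gt(fg_dice, 0.95)
  expect_lt(tail(m$history, 1), head(m$history, 1))
})

test_that("the localization head reaches near-zero error on one sample", {
  sz <- c(16, 24, 24)
  m <- build_model(model_config(tiers = 2, base_channels = 2,
                                patch_size = sz, head_conv_channels = 2,
                                head_fc = c(16, 16, 16), seed = 5))
  ph <- tiny_phantom(n = 3, seed = 6)
  st <- compute_norm_stats(ph$volume)
  vol <- clip_and_normalize(ph$volume, st)
  x <- extract_patch(vol$values, c(15, 8, 15), sz)
  tgt <- c(rep(2, 9), 0.4, 0.9, 0.1)
  tc <- train_config(batch_size = 1, loc_epochs = 1000, loc_lr = 1e-2,
                     loc_gate_fraction = 0.15, seed = 7)
  m2 <- train_localization(m, list(x = list(x), t = list(tgt)), tc,
                           mean_vertebra_volume = 1)
  expect_lt(tail(m2$loc_history, 1), 1e-6)
  # the gate errors out when it excludes everything
  expect_error(train_localization(m, list(x = list(x), t = list(tgt)), tc,
                                  mean_vertebra_volume = 1e9),
               "gate excluded")
})

test_that("augmentation keeps image, labels and offsets consistent", {
  ph <- tiny_phantom(n = 3, seed = 11)
  lm <- ph$labels
  ctr_before <- vertebral_body_center(lm$values == 2L,
                                      spacing = lm$spacing)
  d <- dim(lm$values)
  patch_ctr <- (d - 1) / 2 * lm$spacing
  off_before <- rbind(ctr_before - patch_ctr)
  withr::with_seed(13, {
    au <- augment_patch(ph$volume$values, lm$values, off_before,
                        rotation_deg = 10, scale = 0.2,
                        spacing = lm$spacing)
  })
  expect_equal(dim(au$patch), d)
  expect_true(all(unique(as.vector(au$labels)) %in% 0:3))
  # recompute the transformed instance's center from the warped labels:
  # it must land where the transformed offset points
  ctr_after <- mask_center_mm(au$labels == 2L, lm$spacing)
  predicted <- patch_ctr + au$offsets[1, ]
  expect_lt(sqrt(sum((ctr_after - predicted)^2)), 2.5)
})
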