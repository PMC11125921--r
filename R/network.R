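#' Configuration of the combined localization and segmentation network
#'
#' A single encoder is shared by two branches: a U-Net style
#' encoder-decoder that emits three-class (background/body/boundary)
#' probabilities at patch resolution, and a regression head that consumes
#' the deepest encoder feature map (the bottleneck) through one 1x1x1
#' convolution and four fully connected layers to produce the 1x12
#' localization vector (three center offsets plus three confidences).
#' Leaky-rectifier activations throughout; instance normalization in the
#' segmentation path, batch normalization in the regression head.
#'
#' The parameter count depends only on the channel widths, never on the
#' input volume size: the network is fully patch-based. Channel widths
#' double per tier starting at `base_channels`.
#'
#' @param tiers number of resolution tiers (default 4).
#' @param base_channels channels at full resolution (default 16; reduced
#'   widths such as 4 train in minutes on one CPU).
#' @param patch_size input patch extents (z, y, x); every axis must be
#'   divisible by `2^(tiers - 1)`.
#' @param leaky_slope negative slope of the leaky rectifier.
#' @param head_conv_channels channels of the head's 1x1x1 convolution.
#' @param head_fc widths of the three hidden fully connected layers.
#' @param seed initialization seed.
#' @return A `vertseg_model_config`.
#' @export
model_config <- function(tiers = 4, base_channels = 16,
                         patch_size = c(32, 48, 48), leaky_slope = 0.01,
                         head_conv_channels = 8,
                         head_fc = c(256, 128, 64), seed = 1L) {
  patch_size <- as.integer(patch_size)
  f <- 2^(tiers - 1)
  if (any(patch_size %% f != 0))
    stop("patch_size must be divisible by 2^(tiers-1) per axis")
  structure(list(tiers = as.integer(tiers),
                 base_channels = as.integer(base_channels),
                 patch_size = patch_size, leaky_slope = leaky_slope,
                 head_conv_channels = as.integer(head_conv_channels),
                 head_fc = as.integer(head_fc), n_classes = 3L,
                 seed = as.integer(seed)),
            class = "vertseg_model_config")
}

#' Training configuration
#'
#' Defaults follow the method's published schedule where one exists: the
#' localization head uses a constant learning rate of 1e-4 for 400 epochs
#' with a mean-squared-error loss, and only patches whose segmented
#' volume reaches at least 15 percent of the typical vertebra volume are
#' used. The segmentation schedule (Adam, lr 1e-3) and the augmentation
#' switch are this package's own CPU-scale choices.
#'
#' @param batch_size patches per optimization step (default 32).
#' @param vertebra_fraction minimum fraction of vertebra-containing
#'   patches per batch (default 0.5).
#' @param augment apply random rotation/scaling augmentation.
#' @param aug_rotation_deg rotation range, plus/minus degrees per axis.
#' @param aug_scale scaling range, plus/minus fraction.
#' @param seg_lr,seg_epochs segmentation branch schedule.
#' @param loc_lr,loc_epochs localization head schedule.
#' @param loc_gate_fraction bottleneck gating threshold as a fraction of
#'   the mean vertebra volume (default 0.15), applied as `>=`.
#' @param seed training seed.
#' @return A `vertseg_train_config`.
#' @export
train_config <- function(batch_size = 32, vertebra_fraction = 0.5,
                         augment = FALSE, aug_rotation_deg = 15,
                         aug_scale = 0.25, seg_lr = 1e-3, seg_epochs = 10,
                         loc_lr = 1e-4, loc_epochs = 400,
                         loc_gate_fraction = 0.15, seed = 1L) {
  if (loc_gate_fraction <= 0 || loc_gate_fraction >= 1)
    stop("loc_gate_fraction must be in (0, 1)")
  structure(as.list(environment()), class = "vertseg_train_config")
}

conv_block_init <- function(cin, cout, init = kaiming_normal) {
  list(W = init(27L * cin, cout, 27 * cin), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

#' Build the combined localization and segmentation model
#'
#' Segmentation-path weights use Kaiming initialization with a normal
#' distribution; the localization head uses the Kaiming uniform scheme.
#' Two builds with the same config seed are identical.
#'
#' @param cfg a [model_config()].
#' @return A `vertseg_model`: list with `cfg`, `params` (nested weight
#'   lists) and `bn_stats` (running statistics of the head's batch
#'   normalization).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "vertseg_model_config"))
  T <- cfg$tiers
  ch <- cfg$base_channels * 2^(seq_len(T) - 1)
  with_rng(cfg$seed, {
    enc <- vector("list", T)
    cin <- 1L
    for (t in seq_len(T)) {
      enc[[t]] <- list(c1 = conv_block_init(cin, ch[t]),
                       c2 = conv_block_init(ch[t], ch[t]))
      cin <- ch[t]
    }
    dec <- vector("list", max(T - 1, 0))
    for (t in rev(seq_len(T - 1)))
      dec[[t]] <- list(c1 = conv_block_init(ch[t + 1] + ch[t], ch[t]),
                       c2 = conv_block_init(ch[t], ch[t]))
    outl <- list(W = kaiming_normal(ch[1], cfg$n_classes, ch[1]),
                 b = numeric(cfg$n_classes))
    bdims <- cfg$patch_size %/% (2^(T - 1))
    nb <- prod(bdims) * cfg$head_conv_channels
    hc <- cfg$head_conv_channels
    loc <- list(conv = list(W = kaiming_uniform(ch[T], hc, ch[T]),
                            b = numeric(hc), gamma = rep(1, hc),
                            beta = numeric(hc)),
                fc = list(), fc_out = NULL)
    widths <- c(nb, cfg$head_fc)
    for (i in seq_along(cfg$head_fc)) {
      w <- cfg$head_fc[i]
      loc$fc[[i]] <- list(W = kaiming_uniform(widths[i], w, widths[i]),
                          b = numeric(w), gamma = rep(1, w),
                          beta = numeric(w))
    }
    loc$fc_out <- list(W = kaiming_uniform(widths[length(widths)], 12L,
                                           widths[length(widths)]),
                       b = numeric(12L))
    bn_stats <- list(conv = list(rm = numeric(hc), rv = rep(1, hc)),
                     fc = lapply(cfg$head_fc, function(w)
                       list(rm = numeric(w), rv = rep(1, w))))
    structure(list(cfg = cfg,
                   params = list(seg = list(enc = enc, dec = dec, out = outl),
                                 loc = loc),
                   bn_stats = bn_stats),
              class = "vertseg_model")
  })
}

#' @export
print.vertseg_model <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "unlist")))
  cat(sprintf("<vertseg model> %d tiers, base %d channels, %d parameters\n",
              x$cfg$tiers, x$cfg$base_channels, np))
  invisible(x)
}

conv_block_forward <- function(h, dims, p, slope, keep = FALSE) {
  cv <- conv3_forward(h, dims, p$W, p$b)
  no <- inorm_forward(cv$y, p$gamma, p$beta)
  ac <- leaky_forward(no$y, slope)
  list(y = ac$y,
       cache = if (keep) list(x = h, inorm = no, act = ac) else NULL)
}

conv_block_backward <- function(dy, cache, dims, p, slope) {
  dy <- leaky_backward(dy, cache$act, slope)
  no <- inorm_backward(dy, cache$inorm, p$gamma)
  cv <- conv3_backward(no$dx, NULL, cache$x, dims, p$W)
  list(dx = cv$dx,
       grads = list(W = cv$dW, b = cv$db, gamma = no$dgamma,
                    beta = no$dbeta))
}

# forward through the segmentation branch; returns logits, probabilities,
# the bottleneck feature map and (if train) all caches. The branch is
# fully convolutional: any patch shape divisible by 2^(tiers-1) works,
# so training may use smaller sub-patches than the deployment grid.
seg_forward <- function(model, patch, train = FALSE) {
  cfg <- model$cfg; T <- cfg$tiers; slope <- cfg$leaky_slope
  d0 <- dim(patch)
  if (is.null(d0)) d0 <- cfg$patch_size
  if (any(d0 %% (2^(T - 1)) != 0))
    stop("patch shape must be divisible by 2^(tiers-1) per axis")
  dims <- list(as.integer(d0))
  for (t in seq_len(T - 1)) dims[[t + 1]] <- dims[[t]] %/% 2L
  p <- model$params$seg
  h <- matrix(as.vector(patch), ncol = 1)
  enc_out <- vector("list", T)
  caches <- list(enc = vector("list", T), pool = vector("list", T),
                 dec = vector("list", max(T - 1, 0)))
  for (t in seq_len(T)) {
    b1 <- conv_block_forward(h, dims[[t]], p$enc[[t]]$c1, slope, train)
    b2 <- conv_block_forward(b1$y, dims[[t]], p$enc[[t]]$c2, slope, train)
    enc_out[[t]] <- b2$y
    caches$enc[[t]] <- list(c1 = b1$cache, c2 = b2$cache)
    if (t < T) {
      mp <- maxpool_forward(b2$y, dims[[t]])
      caches$pool[[t]] <- mp
      h <- mp$y
    }
  }
  h <- enc_out[[T]]
  bottleneck <- h
  for (t in rev(seq_len(T - 1))) {
    up <- upsample_forward(h, dims[[t]])
    cat_in <- cbind(up, enc_out[[t]])
    b1 <- conv_block_forward(cat_in, dims[[t]], p$dec[[t]]$c1, slope, train)
    b2 <- conv_block_forward(b1$y, dims[[t]], p$dec[[t]]$c2, slope, train)
    caches$dec[[t]] <- list(c1 = b1$cache, c2 = b2$cache,
                            up_channels = ncol(up), in_n = nrow(h))
    h <- b2$y
  }
  logits <- conv1_forward(h, p$out$W, p$out$b)
  list(logits = logits, probs = softmax_rows(logits),
       bottleneck = bottleneck, final_feat = h, dims = dims,
       caches = if (train) caches else NULL)
}

# backward through the segmentation branch given d loss / d logits
seg_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg; T <- cfg$tiers; slope <- cfg$leaky_slope
  dims <- fwd$dims
  p <- model$params$seg
  ca <- fwd$caches
  g <- list(enc = vector("list", T), dec = vector("list", max(T - 1, 0)),
            out = NULL)
  ov <- conv1_backward(dlogits, fwd$final_feat, p$out$W)
  g$out <- list(W = ov$dW, b = ov$db)
  dh <- ov$dx
  denc <- vector("list", T) # gradient flowing into each encoder output
  for (t in seq_len(T - 1)) {
    b2 <- conv_block_backward(dh, ca$dec[[t]]$c2, dims[[t]], p$dec[[t]]$c2,
                              slope)
    b1 <- conv_block_backward(b2$dx, ca$dec[[t]]$c1, dims[[t]],
                              p$dec[[t]]$c1, slope)
    g$dec[[t]] <- list(c1 = b1$grads, c2 = b2$grads)
    nu <- ca$dec[[t]]$up_channels
    denc[[t]] <- b1$dx[, (nu + 1):ncol(b1$dx), drop = FALSE]
    dh <- upsample_backward(b1$dx[, seq_len(nu), drop = FALSE],
                            ca$dec[[t]]$in_n, dims[[t]])
  }
  denc[[T]] <- dh
  for (t in rev(seq_len(T))) {
    b2 <- conv_block_backward(denc[[t]], ca$enc[[t]]$c2, dims[[t]],
                              p$enc[[t]]$c2, slope)
    b1 <- conv_block_backward(b2$dx, ca$enc[[t]]$c1, dims[[t]],
                              p$enc[[t]]$c1, slope)
    g$enc[[t]] <- list(c1 = b1$grads, c2 = b2$grads)
    if (t > 1) {
      # b1$dx is the gradient at the pooled output of the tier below
      dprev <- maxpool_backward(b1$dx, ca$pool[[t - 1]])
      denc[[t - 1]] <- denc[[t - 1]] + dprev
    }
  }
  g
}

# forward through the localization head for a list of bottleneck maps
# (one per patch); returns the B x 12 output and caches
head_forward <- function(model, bottlenecks, train = FALSE) {
  cfg <- model$cfg; slope <- cfg$leaky_slope
  p <- model$params$loc
  st <- model$bn_stats
  B <- length(bottlenecks)
  nbvox <- nrow(bottlenecks[[1]])
  X <- do.call(rbind, bottlenecks) # (B*nbvox) x C_T
  cv <- conv1_forward(X, p$conv$W, p$conv$b)
  bnc <- bnorm_forward(cv, c(p$conv[c("gamma", "beta")], st$conv), train)
  st$conv <- bnc$p[c("rm", "rv")]
  acc <- leaky_forward(bnc$y, slope)
  H <- matrix(t(acc$y), nrow = B, byrow = TRUE) # flatten per patch
  fc_caches <- list()
  for (i in seq_along(p$fc)) {
    lin <- conv1_forward(H, p$fc[[i]]$W, p$fc[[i]]$b)
    bn <- bnorm_forward(lin, c(p$fc[[i]][c("gamma", "beta")], st$fc[[i]]),
                        train)
    st$fc[[i]] <- bn$p[c("rm", "rv")]
    ac <- leaky_forward(bn$y, slope)
    fc_caches[[i]] <- list(x = H, bn = bn, act = ac)
    H <- ac$y
  }
  out <- conv1_forward(H, p$fc_out$W, p$fc_out$b)
  list(out = out, bn_stats = st,
       caches = if (train) list(X = X, conv = cv, bn = bnc, act = acc,
                                fc = fc_caches, H_last = H, B = B,
                                nbvox = nbvox) else NULL)
}

head_backward <- function(model, fwd, dout) {
  cfg <- model$cfg; slope <- cfg$leaky_slope
  p <- model$params$loc
  ca <- fwd$caches
  g <- list(conv = NULL, fc = vector("list", length(p$fc)), fc_out = NULL)
  ov <- conv1_backward(dout, ca$H_last, p$fc_out$W)
  g$fc_out <- list(W = ov$dW, b = ov$db)
  dH <- ov$dx
  for (i in rev(seq_along(p$fc))) {
    dH <- leaky_backward(dH, ca$fc[[i]]$act, slope)
    bn <- bnorm_backward(dH, ca$fc[[i]]$bn, p$fc[[i]]$gamma)
    lv <- conv1_backward(bn$dx, ca$fc[[i]]$x, p$fc[[i]]$W)
    g$fc[[i]] <- list(W = lv$dW, b = lv$db, gamma = bn$dgamma,
                      beta = bn$dbeta)
    dH <- lv$dx
  }
  # unflatten back to (B*nbvox) x head_conv_channels: row b of dH holds
  # (voxel, channel) pairs with the channel index fastest
  hc <- ncol(ca$act$y)
  dY <- t(array(t(dH), c(hc, ca$nbvox * ca$B)))
  dY <- leaky_backward(dY, ca$act, slope)
  bn <- bnorm_backward(dY, ca$bn, p$conv$gamma)
  cv <- conv1_backward(bn$dx, ca$X, p$conv$W)
  g$conv <- list(W = cv$dW, b = cv$db, gamma = bn$dgamma, beta = bn$dbeta)
  g
}

#' Extract a patch sub-array from a volume array
#'
#' @param values 3D array.
#' @param origin 1-based lower corner (z, y, x).
#' @param size patch extents in voxels.
#' @return The sub-array of extents `size`.
#' @export
extract_patch <- function(values, origin, size) {
  hi <- origin + size - 1
  values[origin[1]:hi[1], origin[2]:hi[2], origin[3]:hi[3], drop = FALSE]
}

# the volume gate of the localization branch: a patch participates only
# when its segmented foreground reaches the given fraction of the typical
# vertebra volume (inclusive)
loc_gate <- function(fg_voxels, gate_fraction, mean_vertebra_volume) {
  fg_voxels >= gate_fraction * mean_vertebra_volume
}

onehot3 <- function(target, n_classes = 3L) {
  v <- as.integer(as.vector(target))
  m <- matrix(0, length(v), n_classes)
  m[cbind(seq_along(v), v + 1L)] <- 1
  m
}

#' Train the segmentation branch with the soft Dice loss
#'
#' Adam optimization of the macro-averaged three-class soft Dice loss on
#' volume patches. If a validation set is given, the parameter state with
#' the lowest validation loss over the epochs is returned; otherwise the
#' final state.
#'
#' @param model a [build_model()] result.
#' @param dataset list with `x` (list of patch arrays) and `y` (list of
#'   integer arrays over \{0, 1, 2\}).
#' @param cfg a [train_config()].
#' @param validation optional dataset of the same shape.
#' @return The trained model, with the loss history in `$history`.
#' @export
train_segmentation <- function(model, dataset, cfg = train_config(),
                               validation = NULL) {
  n <- length(dataset$x)
  if (n == 0) stop("empty training dataset")
  slope <- model$cfg$leaky_slope
  opt <- adam_init(model$params$seg)
  hist <- numeric(0)
  best_loss <- Inf; best_params <- model$params$seg
  with_rng(cfg$seed, {
    for (ep in seq_len(cfg$seg_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        grads <- NULL
        bl <- 0
        for (i in idx) {
          xi <- dataset$x[[i]]; yi <- dataset$y[[i]]
          if (isTRUE(cfg$augment)) {
            au <- augment_patch(xi, yi, NULL, cfg$aug_rotation_deg,
                                cfg$aug_scale)
            xi <- au$patch; yi <- au$labels
          }
          fwd <- seg_forward(model, xi, train = TRUE)
          ls <- soft_dice_loss(fwd$logits, onehot3(yi))
          bl <- bl + ls$loss
          g <- seg_backward(model, fwd, ls$dlogits)
          grads <- if (is.null(grads)) g
                   else params_map2(grads, g, `+`)
        }
        grads <- params_map2(grads, grads, function(a, b) a / length(idx))
        stp <- adam_step(model$params$seg, grads, opt, cfg$seg_lr)
        model$params$seg <- stp$params
        opt <- stp$state
        ep_loss <- ep_loss + bl / length(idx); nb <- nb + 1
      }
      tr_loss <- ep_loss / nb
      if (!is.null(validation)) {
        vl <- mean(vapply(seq_along(validation$x), function(i) {
          fwd <- seg_forward(model, validation$x[[i]])
          soft_dice_loss(fwd$logits, onehot3(validation$y[[i]]))$loss
        }, numeric(1)))
        hist <- c(hist, vl)
        if (vl < best_loss) { best_loss <- vl; best_params <- model$params$seg }
      } else hist <- c(hist, tr_loss)
    }
  })
  if (!is.null(validation)) model$params$seg <- best_params
  model$history <- hist
  model
}

#' Train the localization head on gated bottleneck data
#'
#' The encoder is frozen; only the regression head is optimized, by Adam
#' on the mean-squared error against the 1x12 targets. A patch
#' participates only if its predicted foreground volume is at least
#' `loc_gate_fraction` (default 15 percent) of the typical vertebra
#' volume.
#'
#' @param model a model with a trained segmentation branch.
#' @param dataset list with `x` (patch arrays) and `t` (numeric
#'   12-vectors from [as.double.vertseg_loc_target()]).
#' @param cfg a [train_config()].
#' @param mean_vertebra_volume typical vertebra volume in voxels, from
#'   [mean_vertebra_volume()] of the training reference labels.
#' @return The trained model with `$loc_history` (epoch MSE).
#' @export
train_localization <- function(model, dataset, cfg = train_config(),
                               mean_vertebra_volume) {
  n <- length(dataset$x)
  if (n == 0) stop("empty localization dataset")
  keep <- logical(n)
  bottlenecks <- vector("list", n)
  for (i in seq_len(n)) {
    fwd <- seg_forward(model, dataset$x[[i]])
    fg <- sum(max.col(fwd$probs, ties.method = "first") != 1L)
    keep[i] <- loc_gate(fg, cfg$loc_gate_fraction, mean_vertebra_volume)
    if (keep[i]) bottlenecks[[i]] <- fwd$bottleneck
  }
  if (!any(keep)) stop("the volume gate excluded every patch")
  bn <- bottlenecks[keep]
  targets <- do.call(rbind, dataset$t[keep])
  m <- length(bn)
  opt <- adam_init(model$params$loc)
  hist <- numeric(0)
  with_rng(cfg$seed, {
    for (ep in seq_len(cfg$loc_epochs)) {
      ord <- sample.int(m)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, m, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, m)]
        fwd <- head_forward(model, bn[idx], train = TRUE)
        model$bn_stats <- fwd$bn_stats
        resid <- fwd$out - targets[idx, , drop = FALSE]
        loss <- mean(resid^2)
        g <- head_backward(model, fwd, 2 * resid / length(resid))
        stp <- adam_step(model$params$loc, g, opt, cfg$loc_lr)
        model$params$loc <- stp$params
        opt <- stp$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      hist <- c(hist, ep_loss / nb)
    }
  })
  model$loc_history <- hist
  model
}

#' Run both network branches on one patch
#'
#' One shared forward pass: the segmentation probabilities at patch
#' resolution and the 12-component localization output (offsets in mm
#' from the patch center; confidences clipped to \[0, 1\] at the
#' interface). Deterministic in evaluation mode.
#'
#' @param model a trained model.
#' @param patch numeric array of the model's patch size.
#' @return List with `probs` (array (z, y, x, 3)) and `loc`
#'   (length-12 numeric: top/mid/bottom offsets then confidences).
#' @export
predict_patch <- function(model, patch) {
  ps <- model$cfg$patch_size
  if (!identical(dim(patch), as.integer(ps)))
    stop("patch has the wrong shape")
  fwd <- seg_forward(model, patch)
  hd <- head_forward(model, list(fwd$bottleneck))
  loc <- as.numeric(hd$out)
  loc[10:12] <- pmin(pmax(loc[10:12], 0), 1)
  list(probs = array(fwd$probs, c(ps, model$cfg$n_classes)), loc = loc)
}

#' Jointly augment a patch, its labels and its offset targets
#'
#' Random rotation (independent small angles per axis) and isotropic
#' scaling about the patch center. The intensity patch is resampled
#' trilinearly, labels by nearest neighbour, and offset vectors are
#' rotated and scaled with the image so the regression target stays
#' geometrically consistent.
#'
#' @param patch numeric 3D array.
#' @param labels optional integer 3D array on the same grid.
#' @param offsets optional 3 x 3 matrix of mm offsets (rows are targets).
#' @param rotation_deg maximal absolute rotation per axis (degrees).
#' @param scale maximal absolute fractional scaling.
#' @param spacing voxel spacing (mm).
#' @return List with `patch`, `labels`, `offsets` transformed.
#' @export
augment_patch <- function(patch, labels = NULL, offsets = NULL,
                          rotation_deg = 15, scale = 0.25,
                          spacing = c(2, 0.977, 0.977)) {
  ang <- stats::runif(3, -rotation_deg, rotation_deg) * pi / 180
  s <- 1 + stats::runif(1, -scale, scale)
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  # rotations about the z, y, x axes in (z, y, x) coordinates
  Rz <- rbind(c(1, 0, 0), c(0, cz, -sz), c(0, sz, cz))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(cx, -sx, 0), c(sx, cx, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  d <- dim(patch)
  ctr <- (d - 1) / 2 * spacing
  # target voxel positions relative to the center, pulled back through
  # the inverse transform
  grid <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                                x = seq_len(d[3])))
  pos <- sweep(sweep(grid - 1, 2, spacing, `*`), 2, ctr, `-`)
  src <- pos %*% R / s # R^-1 = t(R); (pos %*% R) = t(t(R) %*% t(pos))
  src_idx <- sweep(sweep(src, 2, ctr, `+`), 2, spacing, `/`) + 1
  out <- array(interp_trilinear(patch, src_idx), d)
  lab_out <- NULL
  if (!is.null(labels)) {
    ri <- pmin(pmax(round(src_idx), 1), matrix(d, nrow(src_idx), 3,
                                               byrow = TRUE))
    inb <- rowSums(round(src_idx) < 1 | sweep(round(src_idx), 2, d, `>`)) == 0
    lv <- labels[ri]
    lv[!inb] <- 0L
    lab_out <- array(lv, d)
  }
  off_out <- if (!is.null(offsets)) t(R %*% t(offsets * s)) else NULL
  list(patch = out, labels = lab_out, offsets = off_out,
       rotation = ang * 180 / pi, scale = s)
}

# trilinear interpolation of a 3D array at fractional (z,y,x) indices;
# outside samples take the value 0
interp_trilinear <- function(a, idx) {
  d <- dim(a)
  inb <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- numeric(nrow(idx))
  ii <- idx[inb, , drop = FALSE]
  f0 <- pmin(floor(ii), matrix(pmax(d - 1, 1), nrow(ii), 3, byrow = TRUE))
  w <- ii - f0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    cz <- pmin(f0[, 1] + dz, d[1]); cyy <- pmin(f0[, 2] + dy, d[2])
    cxx <- pmin(f0[, 3] + dx, d[3])
    wt <- (if (dz) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dx) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * a[cbind(cz, cyy, cxx)]
  }
  out[inb] <- acc
  out
}
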