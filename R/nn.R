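# Minimal 3D conv-net primitives.
#
# Feature maps are matrices (Nvox x C) with voxels flattened in R's
# column-major order of an array with dim (nz, ny, nx), i.e. z fastest.
# One patch is processed at a time; 3x3x3 convolution is realized as an
# im2col gather followed by one BLAS matrix multiply, which keeps all
# heavy arithmetic vectorized. Every layer has an explicit backward pass.

.vs_nn_cache <- new.env(parent = emptyenv())

# Nvox x 27 matrix of source linear indices for a 3x3x3 neighbourhood
# (zero-padding: 0 marks out-of-bounds). Cached per shape.
conv3_idx <- function(dims) {
  key <- paste0("c3_", paste(dims, collapse = "x"))
  if (!is.null(.vs_nn_cache[[key]])) return(.vs_nn_cache[[key]])
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  n <- nz * ny * nx
  v <- seq_len(n) - 1L
  z <- v %% nz; y <- (v %/% nz) %% ny; x <- v %/% (nz * ny)
  idx <- matrix(0L, n, 27L)
  t <- 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    t <- t + 1L
    zi <- z + dz; yi <- y + dy; xi <- x + dx
    ok <- zi >= 0L & zi < nz & yi >= 0L & yi < ny & xi >= 0L & xi < nx
    lin <- zi + nz * (yi + ny * xi) + 1L
    idx[, t] <- ifelse(ok, lin, 0L)
  }
  .vs_nn_cache[[key]] <- idx
  idx
}

conv3_forward <- function(x, dims, W, b) {
  list(y = cpp_conv3_forward(x, conv3_idx(dims), W, b))
}

# the im2col matrix is rebuilt inside the compiled backward pass rather
# than cached, trading a second gather for a much smaller memory footprint
conv3_backward <- function(dy, cache, x, dims, W) {
  cpp_conv3_backward(dy, x, conv3_idx(dims), W)
}

conv1_forward <- function(x, W, b) sweep(x %*% W, 2, b, `+`)
conv1_backward <- function(dy, x, W)
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))

leaky_forward <- function(x, slope) {
  y <- x
  neg <- x < 0
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg)
}
leaky_backward <- function(dy, cache, slope) {
  dx <- dy
  dx[cache$neg] <- slope * dy[cache$neg]
  dx
}

# instance normalization: per channel over all voxels of the patch
inorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xh, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, xh = xh, istd = istd)
}
inorm_backward <- function(dy, cache, gamma) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xh)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2, gamma, `*`)
  t1 <- sweep(dxh, 2, colMeans(dxh))
  t2 <- sweep(cache$xh, 2, colMeans(dxh * cache$xh), `*`)
  dx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# batch normalization over rows (used in the localization head), with
# running statistics for evaluation mode
bnorm_forward <- function(x, p, train, momentum = 0.1, eps = 1e-5) {
  if (train && nrow(x) > 1) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    p$rm <- (1 - momentum) * p$rm + momentum * mu
    p$rv <- (1 - momentum) * p$rv + momentum * v * nrow(x) / (nrow(x) - 1)
  } else {
    mu <- p$rm; v <- p$rv
    xc <- sweep(x, 2, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xh, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(y = y, xh = xh, istd = istd, p = p)
}
bnorm_backward <- function(dy, cache, gamma) {
  dgamma <- colSums(dy * cache$xh)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2, gamma, `*`)
  t1 <- sweep(dxh, 2, colMeans(dxh))
  t2 <- sweep(cache$xh, 2, colMeans(dxh * cache$xh), `*`)
  dx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# 2x2x2 max pooling source indices: (Nout x 8), cached per input shape
pool_idx <- function(dims) {
  key <- paste0("mp_", paste(dims, collapse = "x"))
  if (!is.null(.vs_nn_cache[[key]])) return(.vs_nn_cache[[key]])
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  oz <- nz %/% 2L; oy <- ny %/% 2L; ox <- nx %/% 2L
  n <- oz * oy * ox
  v <- seq_len(n) - 1L
  z <- (v %% oz) * 2L; y <- ((v %/% oz) %% oy) * 2L
  x <- (v %/% (oz * oy)) * 2L
  idx <- matrix(0L, n, 8L)
  t <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    t <- t + 1L
    idx[, t] <- (z + dz) + nz * ((y + dy) + ny * (x + dx)) + 1L
  }
  .vs_nn_cache[[key]] <- idx
  idx
}

maxpool_forward <- function(x, dims) {
  idx <- pool_idx(dims)
  n <- nrow(idx); cin <- ncol(x)
  best <- x[idx[, 1], , drop = FALSE]
  arg <- matrix(idx[, 1], n, cin)
  for (t in 2:8) {
    cand <- x[idx[, t], , drop = FALSE]
    better <- cand > best
    best[better] <- cand[better]
    src <- matrix(idx[, t], n, cin)
    arg[better] <- src[better]
  }
  list(y = best, arg = arg, in_n = nrow(x))
}
maxpool_backward <- function(dy, cache) {
  cin <- ncol(dy)
  dx <- matrix(0, cache$in_n, cin)
  for (c in seq_len(cin)) {
    # argmax positions are unique per output voxel and channel
    dx[cache$arg[, c], c] <- dy[, c]
  }
  dx
}

# nearest-neighbour 2x upsampling: child -> parent map, cached
upsample_idx <- function(out_dims) {
  key <- paste0("up_", paste(out_dims, collapse = "x"))
  if (!is.null(.vs_nn_cache[[key]])) return(.vs_nn_cache[[key]])
  nz <- out_dims[1]; ny <- out_dims[2]; nx <- out_dims[3]
  iz <- nz %/% 2L; iy <- ny %/% 2L
  n <- nz * ny * nx
  v <- seq_len(n) - 1L
  z <- (v %% nz) %/% 2L; y <- ((v %/% nz) %% ny) %/% 2L
  x <- (v %/% (nz * ny)) %/% 2L
  parent <- z + iz * (y + iy * x) + 1L
  .vs_nn_cache[[key]] <- parent
  parent
}
upsample_forward <- function(x, out_dims) {
  parent <- upsample_idx(out_dims)
  x[parent, , drop = FALSE]
}
upsample_backward <- function(dy, in_n, out_dims) {
  parent <- upsample_idx(out_dims)
  dx <- matrix(0, in_n, ncol(dy))
  for (c in seq_len(ncol(dy)))
    dx[, c] <- as.vector(rowsum(dy[, c], parent, reorder = TRUE))
  dx
}

softmax_rows <- function(z) {
  m <- z[, 1]
  for (j in seq_len(ncol(z))[-1]) m <- pmax(m, z[, j])
  e <- exp(z - m)
  e / rowSums(e)
}

# macro-averaged soft Dice loss over classes, with gradient wrt logits
soft_dice_loss <- function(logits, onehot, eps = 1e-5) {
  p <- softmax_rows(logits)
  inter <- colSums(p * onehot)
  sums <- colSums(p) + colSums(onehot)
  dice_c <- (2 * inter + eps) / (sums + eps)
  loss <- 1 - mean(dice_c)
  # d dice_c / d p_ic, then through softmax
  nc <- ncol(p)
  dp <- matrix(0, nrow(p), nc)
  for (c in seq_len(nc)) {
    dp[, c] <- -(2 * onehot[, c] * (sums[c] + eps) - (2 * inter[c] + eps)) /
      (sums[c] + eps)^2 / nc
  }
  dz <- p * (dp - rowSums(dp * p))
  list(loss = loss, dlogits = dz, dice_per_class = dice_c)
}

# ---- parameter initialization and Adam over nested parameter lists ----

kaiming_normal <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}
kaiming_uniform <- function(nr, nc, fan_in) {
  b <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

params_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- params_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}
params_zero_like <- function(a) {
  if (is.list(a)) lapply(a, params_zero_like) else a * 0
}

adam_init <- function(params) {
  list(m = params_zero_like(params), v = params_zero_like(params), t = 0)
}
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- params_map2(state$m, state$v, function(m, v)
    (m / bc1) / (sqrt(v / bc2) + eps))
  params <- params_map2(params, mh, function(p, u) p - lr * u)
  list(params = params, state = state)
}
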