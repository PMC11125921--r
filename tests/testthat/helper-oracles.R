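# Brute-force reference implementations used as independent oracles.
# All of them are deliberately naive (set arithmetic, exhaustive search)
# and are only ever run on small grids.

brute_erode <- function(mask, offsets) {
  mask <- mask != 0
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    ok <- TRUE
    for (i in seq_len(nrow(offsets))) {
      w <- v + offsets[i, ]
      if (any(w < 1) || any(w > d) || !mask[w[1], w[2], w[3]]) {
        ok <- FALSE; break
      }
    }
    out[v[1], v[2], v[3]] <- ok
  }
  out
}

brute_dilate <- function(mask, offsets) {
  mask <- mask != 0
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    for (i in seq_len(nrow(offsets))) {
      w <- v + offsets[i, ]
      if (all(w >= 1) && all(w <= d)) out[w[1], w[2], w[3]] <- TRUE
    }
  }
  out
}

brute_open <- function(mask, offsets) brute_dilate(brute_erode(mask, offsets), offsets)

# exhaustive nearest-foreground Euclidean distance (mm)
brute_edt <- function(mask, spacing) {
  mask <- mask != 0
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(fg) == 0) return(out)
  fg_mm <- sweep(fg - 1, 2, spacing, `*`)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  all_mm <- sweep(all_idx - 1, 2, spacing, `*`)
  for (r in seq_len(nrow(all_idx))) {
    dif <- sweep(fg_mm, 2, all_mm[r, ])
    out[all_idx[r, , drop = FALSE]] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

brute_signed_distance <- function(mask, spacing) {
  brute_edt(mask, spacing) - brute_edt(!(mask != 0), spacing)
}

# priority-flood watershed by repeated minimum extraction (Dijkstra-like)
brute_watershed <- function(dmap, mask, seed_idx, connectivity = 26) {
  mask <- mask != 0
  d <- dim(mask)
  lab <- array(0L, d)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  frontier_v <- numeric(0); frontier_i <- matrix(0L, 0, 3)
  frontier_l <- integer(0); frontier_o <- integer(0)
  push_ctr <- 0L
  push <- function(v, l) {
    push_ctr <<- push_ctr + 1L
    frontier_v <<- c(frontier_v, dmap[v[1], v[2], v[3]])
    frontier_i <<- rbind(frontier_i, v)
    frontier_l <<- c(frontier_l, l)
    frontier_o <<- c(frontier_o, push_ctr)
  }
  for (s in seq_len(nrow(seed_idx))) push(seed_idx[s, ], s)
  while (length(frontier_v)) {
    j <- order(frontier_v, frontier_o)[1]
    v <- frontier_i[j, ]; l <- frontier_l[j]
    frontier_v <- frontier_v[-j]; frontier_i <- frontier_i[-j, , drop = FALSE]
    frontier_l <- frontier_l[-j]; frontier_o <- frontier_o[-j]
    if (lab[v[1], v[2], v[3]] != 0L) next
    lab[v[1], v[2], v[3]] <- l
    for (i in seq_len(nrow(off))) {
      w <- v + off[i, ]
      if (any(w < 1) || any(w > d)) next
      if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) push(w, l)
    }
  }
  lab
}

# linear-interpolated percentile of a sorted sample (order statistics)
brute_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# solid ball mask centered in a cube grid
ball_mask <- function(n, r, spacing = c(1, 1, 1), center = NULL) {
  if (is.null(center)) center <- (n - 1) / 2 * spacing
  g <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  pos <- sweep(as.matrix(g) - 1, 2, spacing, `*`)
  array(colSums((t(pos) - center)^2) <= r^2, c(n, n, n))
}

# deterministic small random mask
random_mask <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, array(stats::runif(n^3) < p, c(n, n, n)))
}

tiny_phantom <- function(n = 4, seed = 1, ...) {
  generate_spine_phantom(phantom_spec(n_vertebrae = n, seed = seed, ...))
}
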