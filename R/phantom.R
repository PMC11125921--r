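#' Specification of a synthetic spine phantom
#'
#' Describes a stack of 3-18 vertebra-like objects: an axis-aligned
#' ellipsoidal body plus a thin posterior box process, with inter-center
#' z-spacing drawn from a Gaussian. Optional entries flatten (collapse)
#' single vertebrae or bridge (fuse) adjacent pairs, which are the failure
#' precursors the post-processing stages must handle. Intensities are a
#' two-level piecewise-constant CT-like model (soft tissue vs. bone) with
#' additive Gaussian noise; the model is deliberately simple and is not
#' meant to be radiometrically realistic.
#'
#' @param n_vertebrae number of vertebrae, between 3 and 18.
#' @param body_radii ellipsoid semi-axes in mm, (z, y, x).
#' @param process_length posterior process length in mm.
#' @param spacing_mean,spacing_sd mean and sd (mm) of the Gaussian
#'   inter-center z-distance. `spacing_mean` must exceed twice the body
#'   z-radius so that non-fused neighbours stay disjoint.
#' @param intensity_levels named vector `c(soft = , bone = )` of HU-like
#'   intensity plateaus.
#' @param noise_sd additive Gaussian noise sd.
#' @param collapse_indices vertebra indices whose z-extent is flattened to
#'   45 percent of nominal.
#' @param fuse_pairs list of length-2 integer vectors of adjacent indices
#'   to bridge with a bony connection.
#' @param voxel_spacing working-grid voxel size in mm, (z, y, x).
#' @param seed integer seed; the same spec yields bit-identical phantoms.
#' @return A `vertseg_phantom_spec` list.
#' @export
phantom_spec <- function(n_vertebrae = 5,
                         body_radii = c(11, 14, 16),
                         process_length = 20,
                         spacing_mean = 30,
                         spacing_sd = 2,
                         intensity_levels = c(soft = 40, bone = 400),
                         noise_sd = 20,
                         collapse_indices = integer(0),
                         fuse_pairs = list(),
                         voxel_spacing = c(2, 0.977, 0.977),
                         seed = 1L) {
  if (n_vertebrae < 3 || n_vertebrae > 18)
    stop("n_vertebrae must be in [3, 18]")
  if (spacing_mean <= 2 * body_radii[1])
    stop("spacing_mean must exceed twice the body z-radius")
  if (length(fuse_pairs) && !is.list(fuse_pairs)) fuse_pairs <- list(fuse_pairs)
  for (fp in fuse_pairs)
    if (length(fp) != 2 || abs(diff(fp)) != 1)
      stop("fuse_pairs entries must be adjacent index pairs")
  structure(list(n_vertebrae = as.integer(n_vertebrae),
                 body_radii = as.numeric(body_radii),
                 process_length = process_length,
                 spacing_mean = spacing_mean, spacing_sd = spacing_sd,
                 intensity_levels = intensity_levels, noise_sd = noise_sd,
                 collapse_indices = as.integer(collapse_indices),
                 fuse_pairs = fuse_pairs,
                 voxel_spacing = as.numeric(voxel_spacing),
                 seed = as.integer(seed)),
            class = "vertseg_phantom_spec")
}

#' Generate a synthetic spine phantom
#'
#' Builds the CT-like intensity volume and the matching instance label map
#' described by a [phantom_spec()]. Instances are labelled 1..n from
#' bottom to top.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `volume` (a [volume()]) and `labels`
#'   (a [labelmap()]).
#' @examples
#' ph <- generate_spine_phantom(phantom_spec(n_vertebrae = 4, seed = 7))
#' ph$labels
#' @export
generate_spine_phantom <- function(spec) {
  stopifnot(inherits(spec, "vertseg_phantom_spec"))
  with_rng(spec$seed, {
    n <- spec$n_vertebrae
    r <- spec$body_radii
    sp <- spec$voxel_spacing
    # inter-center gaps; clipped away from overlap (non-fused neighbours
    # must not intersect)
    min_gap <- 2.2 * r[1]
    gaps <- pmax(stats::rnorm(n - 1, spec$spacing_mean, spec$spacing_sd),
                 min_gap)
    z_margin <- 1.5 * r[1] + 6
    centers_z <- z_margin + r[1] + c(0, cumsum(gaps))
    # posterior process extends toward +y
    y_c <- r[2] + 8
    x_c <- r[3] + spec$process_length / 2 + 4
    extent_mm <- c(max(centers_z) + r[1] + z_margin,
                   y_c + r[2] + spec$process_length + 8,
                   2 * x_c)
    dims <- pmax(ceiling(extent_mm / sp), 8)
    # physical coordinate grids
    zc <- (seq_len(dims[1]) - 1) * sp[1]
    yc <- (seq_len(dims[2]) - 1) * sp[2]
    xc <- (seq_len(dims[3]) - 1) * sp[3]
    lab <- array(0L, dims)
    rz_all <- rep(r[1], n)
    rz_all[spec$collapse_indices] <- 0.45 * r[1]
    for (i in seq_len(n)) {
      rz <- rz_all[i]
      z0 <- centers_z[i]
      iz <- which(abs(zc - z0) <= rz)
      iy <- which(abs(yc - y_c) <= r[2] + spec$process_length)
      ix <- which(abs(xc - x_c) <= r[3])
      if (!length(iz) || !length(iy) || !length(ix)) next
      gz <- (zc[iz] - z0) / rz
      gy <- (yc[iy] - y_c) / r[2]
      gx <- (xc[ix] - x_c) / r[3]
      body <- outer(outer(gz^2, gy^2, `+`), gx^2, `+`) <= 1
      # thin posterior process: 3-voxel slab in x, half body height in z
      proc_z <- abs(zc[iz] - z0) <= rz / 2
      proc_y <- yc[iy] >= y_c + r[2] - 3 &
        yc[iy] <= y_c + r[2] + spec$process_length
      proc_x <- abs(xc[ix] - x_c) <= 1.5 * sp[3]
      proc <- outer(outer(proc_z, proc_y, `&`), proc_x, `&`)
      sub <- lab[iz, iy, ix, drop = FALSE]
      sub[(body | proc) & sub == 0L] <- i
      lab[iz, iy, ix] <- sub
    }
    # bony bridges for fused pairs (assigned to the lower instance)
    for (fp in spec$fuse_pairs) {
      i <- min(fp)
      iz <- which(zc >= centers_z[i] & zc <= centers_z[i + 1])
      iy <- which(abs(yc - y_c) <= 3)
      ix <- which(abs(xc - x_c) <= 1.5 * sp[3])
      sub <- lab[iz, iy, ix, drop = FALSE]
      sub[sub == 0L] <- i
      lab[iz, iy, ix] <- sub
    }
    vol <- array(spec$intensity_levels[["soft"]], dims)
    vol[lab > 0L] <- spec$intensity_levels[["bone"]]
    vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)
    list(volume = volume(vol, spacing = sp),
         labels = labelmap(lab, spacing = sp))
  })
}

#' Simulate accumulated center votes around known vertebra centers
#'
#' Emulates the cloud of per-patch center predictions that the trained
#' localization head produces: each true center receives
#' `votes_per_center` Gaussian-perturbed copies with confidence weights
#' in (0, 1].
#'
#' @param centers numeric matrix (k x 3) of true centers in mm, (z, y, x);
#'   at least 3 rows.
#' @param votes_per_center positive number of votes per center.
#' @param position_sd isotropic positional noise sd in mm.
#' @param confidence_model function `n -> n weights in (0, 1]`; default
#'   draws uniformly from (0.05, 1].
#' @param seed integer seed.
#' @return A tibble with columns `z`, `y`, `x`, `weight` and
#'   `true_cluster` (the generating center's row index).
#' @export
generate_center_votes <- function(centers, votes_per_center = 20,
                                  position_sd = 2,
                                  confidence_model = NULL, seed = 1L) {
  centers <- rbind_points(centers)
  if (nrow(centers) < 3) stop("need at least 3 centers")
  if (votes_per_center <= 0) stop("votes_per_center must be positive")
  if (is.null(confidence_model))
    confidence_model <- function(n) stats::runif(n, 0.05, 1)
  with_rng(seed, {
    k <- nrow(centers)
    m <- as.integer(votes_per_center)
    idx <- rep(seq_len(k), each = m)
    pos <- centers[idx, , drop = FALSE] +
      matrix(stats::rnorm(3 * k * m, 0, position_sd), ncol = 3)
    w <- confidence_model(k * m)
    if (any(w <= 0) || any(w > 1))
      stop("confidence_model must return weights in (0, 1]")
    tibble::tibble(z = pos[, 1], y = pos[, 2], x = pos[, 3],
                   weight = w, true_cluster = idx)
  })
}
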