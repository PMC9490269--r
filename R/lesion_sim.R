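#' Lesion simulation for pre-training
#'
#' New MS lesions are rare and small; the simulator counters this class
#' imbalance by inserting synthetic hyperintense lesions into lesion-free
#' images and deforming them, producing pairs with known ground truth.
#'
#' @name lesion_sim
NULL

# ---------------------------------------------------------------------------
# Small morphology toolbox (ball structuring elements, voxel units)
# ---------------------------------------------------------------------------

offsets_ball <- function(radius, nd) {
  if (radius <= 0) return(matrix(0L, nrow = 1, ncol = nd))
  r <- ceiling(radius)
  g <- do.call(expand.grid, rep(list(seq(-r, r)), nd))
  g <- as.matrix(g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE])
  storage.mode(g) <- "integer"
  g
}

#' Morphological erosion / dilation with a ball structuring element
#'
#' Voxels outside the array are treated as background.
#'
#' @param mask logical array (2-D or 3-D).
#' @param radius ball radius in voxels.
#' @export
erode_mask <- function(mask, radius) {
  offs <- offsets_ball(radius, length(dim(mask)))
  out <- array(TRUE, dim = dim(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_arr(mask, offs[i, ], fill = FALSE)
  }
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius) {
  offs <- offsets_ball(radius, length(dim(mask)))
  out <- array(FALSE, dim = dim(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_arr(mask, offs[i, ], fill = FALSE)
  }
  out
}

# Generic array shift with constant fill.
shift_arr <- function(arr, off, fill = 0) {
  d <- dim(arr)
  nd <- length(d)
  out <- array(fill, dim = d)
  idx_dst <- idx_src <- vector("list", nd)
  for (a in seq_len(nd)) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      idx_dst[[a]] <- seq_len(d[a] - o)
      idx_src[[a]] <- seq_len(d[a] - o) + o
    } else {
      idx_dst[[a]] <- seq_len(d[a] + o) - o
      idx_src[[a]] <- seq_len(d[a] + o)
    }
  }
  if (nd == 2L) {
    out[idx_dst[[1]], idx_dst[[2]]] <- arr[idx_src[[1]], idx_src[[2]]]
  } else {
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

# Min-max normalization to [0, 1] over a mask (default: whole grid).
minmax_normalize <- function(vals, mask = NULL) {
  ref <- if (is.null(mask)) vals else vals[mask]
  lo <- min(ref); hi <- max(ref)
  if (hi <= lo) return(vals * 0)
  pmin(pmax((vals - lo) / (hi - lo), 0), 1)
}

#' Candidate-location mask for lesion insertion
#'
#' Union of the two brain masks, intersected with the voxels whose min-max
#' normalized intensity exceeds `threshold` in the baseline and (by default)
#' also the follow-up image — this removes the dark ventricles — and finally
#' shrunk by morphological erosion with a ball so simulated lesions cannot
#' protrude beyond the brain edge.
#'
#' @param B,F_img baseline / follow-up (`image_volume` or array).
#' @param brain_B,brain_F logical brain masks.
#' @param erosion_radius ball radius in voxels (default 2).
#' @param threshold normalized-intensity cut-off (default 0.1).
#' @param apply_to `"both"` thresholds both images, `"baseline"` only B.
#' @return Logical array with a `provenance` attribute recording the steps.
#' @export
candidate_mask <- function(B, F_img = B, brain_B, brain_F = brain_B,
                           erosion_radius = 2, threshold = 0.1,
                           apply_to = c("both", "baseline")) {
  apply_to <- match.arg(apply_to)
  Bv <- vol_values(B); Fv <- vol_values(F_img)
  stopifnot(identical(dim(Bv), dim(brain_B)), identical(dim(Fv), dim(brain_F)))
  brain <- brain_B | brain_F
  nB <- minmax_normalize(Bv)
  keep <- brain & (nB > threshold)
  if (apply_to == "both") {
    nF <- minmax_normalize(Fv)
    keep <- keep & (nF > threshold)
  }
  out <- erode_mask(keep, erosion_radius)
  if (!any(out)) {
    stop("candidate mask is empty; try a smaller erosion radius")
  }
  attr(out, "provenance") <- list(brain_union = TRUE, threshold = threshold,
                                  apply_to = apply_to,
                                  erosion_radius = erosion_radius)
  out
}

random_rotation <- function(nd) {
  if (nd == 2L) {
    th <- runif(1, 0, 2 * pi)
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
}

#' Insert simulated lesions
#'
#' Draws a lesion count uniformly in 1..5, samples centers uniformly from the
#' candidate mask and adds, per lesion, a compact-support Gaussian-ellipsoid
#' intensity bump: the profile `a * exp(-q/2)` is shifted and truncated at
#' the `mask_level` iso-contour (and rescaled back to peak `a`), so the added
#' intensity is exactly zero outside the returned lesion mask.
#'
#' @param img image to lesion (`image_volume` or array).
#' @param cand logical candidate mask (same grid).
#' @param count lesion count; `NULL` samples uniformly from 1..5.
#' @param semi_axes_range range of ellipsoid semi-axes (voxels).
#' @param peak_range peak offset as a fraction of the robust intensity range
#'   (1st to 99th percentile).
#' @param mask_level iso-level (fraction of the peak) defining the lesion
#'   mask; 0.5 gives the full-width-half-maximum support.
#' @param seed optional integer seed.
#' @return List with `image`, `mask` (logical), `lesions` (data frame of
#'   center coordinates, semi-axes and peak offsets).
#' @export
insert_lesions <- function(img, cand, count = NULL,
                           semi_axes_range = c(1.5, 5),
                           peak_range = c(0.3, 0.7), mask_level = 0.5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- vol_values(img)
  d <- dim(vals)
  nd <- length(d)
  stopifnot(identical(dim(cand), d))
  if (!any(cand)) stop("candidate mask is empty")
  if (is.null(count)) count <- sample.int(5L, 1L)
  if (count < 1 || count > 5) stop("lesion count must be in 1..5")
  cand_idx <- which(cand)
  if (length(cand_idx) < count) {
    stop("candidate mask too small for the requested lesion count")
  }
  q <- quantile(vals, c(0.01, 0.99), names = FALSE)
  robust_range <- max(q[2] - q[1], .Machine$double.eps)
  centers <- arrayInd(sample(cand_idx, count), d)
  lesion_mask <- array(FALSE, dim = d)
  qcut <- -2 * log(mask_level)
  rows <- vector("list", count)
  for (li in seq_len(count)) {
    s <- runif(nd, semi_axes_range[1], semi_axes_range[2])
    a <- runif(1, peak_range[1], peak_range[2]) * robust_range
    if (a <= 0) stop("lesion peak offset must be positive")
    R <- random_rotation(nd)
    ctr <- centers[li, ]
    rad <- ceiling(max(s) * sqrt(qcut)) + 1L
    rng <- lapply(seq_len(nd), function(ax) {
      seq(max(1L, ctr[ax] - rad), min(d[ax], ctr[ax] + rad))
    })
    grid <- as.matrix(do.call(expand.grid, rng))
    rel <- sweep(grid, 2, ctr)
    y <- rel %*% R
    qv <- rowSums(sweep(y^2, 2, s^2, "/"))
    prof <- pmax(exp(-qv / 2) - mask_level, 0) * a / (1 - mask_level)
    lin <- grid[, 1]
    for (ax in 2:nd) lin <- lin + (grid[, ax] - 1L) * prod(d[seq_len(ax - 1L)])
    vals[lin] <- vals[lin] + prof
    lesion_mask[lin] <- lesion_mask[lin] | (prof > 0)
    rows[[li]] <- c(ctr, s, a)
  }
  les <- as.data.frame(do.call(rbind, rows))
  names(les) <- c(paste0("center", seq_len(nd)), paste0("semi_axis", seq_len(nd)),
                  "peak")
  list(image = vol_like(vals, img), mask = lesion_mask, lesions = les)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of an array (separable, replicate borders)
#' @param arr numeric array; `sigma` in voxels; `axes` 1-based axes.
#' @export
gaussian_smooth <- function(arr, sigma, axes = seq_along(dim(arr))) {
  cpp_sepconv(as.double(arr), as.integer(dim(arr)),
              gauss_kernel(sigma), as.integer(axes))
}

#' Random elastic deformation
#'
#' Gaussian-smoothed white-noise displacement field, rescaled so the maximum
#' displacement magnitude equals `amplitude` voxels, applied to the image.
#'
#' @param img image (`image_volume` or array, 2-D or 3-D).
#' @param amplitude maximum displacement (voxels); 0 returns the input.
#' @param smoothing Gaussian sigma of the field (voxels).
#' @param seed optional seed.
#' @return List with `image` (deformed) and `field` (the deformation used).
#' @export
elastic_deform <- function(img, amplitude = 4, smoothing = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- vol_values(img)
  d <- dim(vals)
  nd <- length(d)
  u <- array(0, dim = c(d, nd))
  if (amplitude > 0) {
    for (k in seq_len(nd)) {
      field_component(u, k) <- gaussian_smooth(array(rnorm(prod(d)), d),
                                               smoothing)
    }
    mag <- sqrt(Reduce(`+`, lapply(seq_len(nd),
                                   function(k) field_component(u, k)^2)))
    mmax <- max(mag)
    if (mmax > 0) u <- u * (amplitude / mmax)
  }
  list(image = vol_like(warp_image(vals, u), img), field = u)
}

# ---------------------------------------------------------------------------
# Augmentations
# ---------------------------------------------------------------------------

rigid_sampling_field <- function(d, theta_deg = 0, shift = c(0, 0)) {
  nd <- length(d)
  u <- array(0, dim = c(d, nd))
  ctr <- (d[1:2] + 1) / 2
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ii <- matrix(seq_len(d[1]), d[1], d[2])
  jj <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  p1 <- ii - ctr[1]; p2 <- jj - ctr[2]
  t1 <- R[1, 1] * p1 + R[1, 2] * p2 + shift[1]
  t2 <- R[2, 1] * p1 + R[2, 2] * p2 + shift[2]
  u1 <- t1 - p1; u2 <- t2 - p2
  if (nd == 2L) {
    u[, , 1] <- u1; u[, , 2] <- u2
  } else {
    for (k in seq_len(d[3])) {
      u[, , k, 1] <- u1; u[, , k, 2] <- u2
    }
  }
  list(u = u, R = R)
}

# Transform a ground-truth displacement field under the same rigid resampling
# applied to both images: u'(x) = R^T u(T(x)).
transform_gt_field <- function(gt, rig) {
  nd <- field_ndim(gt)
  sdim <- field_spatial_dim(gt)
  samp <- lapply(seq_len(nd), function(k) {
    cpp_warp(as.double(field_component(gt, k)), as.integer(sdim),
             as.double(rig$u), 0L)
  })
  out <- gt * 0
  Rt <- t(rig$R)
  field_component(out, 1) <- Rt[1, 1] * samp[[1]] + Rt[1, 2] * samp[[2]]
  field_component(out, 2) <- Rt[2, 1] * samp[[1]] + Rt[2, 2] * samp[[2]]
  if (nd == 3L) field_component(out, 3) <- samp[[3]]
  out
}

#' Adaptive histogram equalization (tile-based, clipped)
#'
#' Contrast-limited equalization on a tile grid with bilinear blending of
#' neighbouring tile mappings; applied per axial slice for 3-D input.
#'
#' @param img array; `tiles` tile grid; `clip` clip limit as a fraction of
#'   tile pixel count; `nbins` histogram bins.
#' @export
adaptive_hist_eq <- function(img, tiles = c(8, 8), clip = 0.02,
                             nbins = 256L) {
  vals <- vol_values(img)
  d <- dim(vals)
  if (length(d) == 3L) {
    out <- vals
    for (k in seq_len(d[3])) out[, , k] <- adaptive_hist_eq(vals[, , k],
                                                            tiles, clip, nbins)
    return(vol_like(out, img))
  }
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) return(vol_like(vals, img))
  bin <- pmin(pmax(floor((vals - lo) / (hi - lo) * nbins) + 1L, 1L), nbins)
  tb1 <- floor(seq(0, d[1], length.out = tiles[1] + 1))
  tb2 <- floor(seq(0, d[2], length.out = tiles[2] + 1))
  luts <- array(0, dim = c(tiles[1], tiles[2], nbins))
  ctr1 <- (tb1[-1] + tb1[-length(tb1)] + 1) / 2
  ctr2 <- (tb2[-1] + tb2[-length(tb2)] + 1) / 2
  for (ti in seq_len(tiles[1])) {
    for (tj in seq_len(tiles[2])) {
      sub <- bin[(tb1[ti] + 1):tb1[ti + 1], (tb2[tj] + 1):tb2[tj + 1]]
      h <- tabulate(sub, nbins)
      lim <- max(1, clip * length(sub))
      excess <- sum(pmax(h - lim, 0))
      h <- pmin(h, lim) + excess / nbins
      cdf <- cumsum(h) / sum(h)
      luts[ti, tj, ] <- lo + cdf * (hi - lo)
    }
  }
  ii <- matrix(seq_len(d[1]), d[1], d[2])
  jj <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  f1 <- stats::approx(ctr1, seq_along(ctr1), xout = as.numeric(ii),
                      rule = 2)$y
  f2 <- stats::approx(ctr2, seq_along(ctr2), xout = as.numeric(jj),
                      rule = 2)$y
  i0 <- pmax(pmin(floor(f1), tiles[1] - 1L), 1L)
  j0 <- pmax(pmin(floor(f2), tiles[2] - 1L), 1L)
  w1 <- pmin(pmax(f1 - i0, 0), 1)
  w2 <- pmin(pmax(f2 - j0, 0), 1)
  i1 <- pmin(i0 + 1L, tiles[1])
  j1 <- pmin(j0 + 1L, tiles[2])
  pick <- function(ti, tj) luts[cbind(ti, tj, as.integer(bin))]
  out <- (1 - w1) * (1 - w2) * pick(i0, j0) +
    w1 * (1 - w2) * pick(i1, j0) +
    (1 - w1) * w2 * pick(i0, j1) +
    w1 * w2 * pick(i1, j1)
  vol_like(array(out, d), img)
}

#' Random augmentation of an image pair
#'
#' Applies, each with its configured probability: Gaussian noise, additive
#' brightness change and a linear brightness gradient (all restricted to the
#' brain region, drawn independently per image), adaptive histogram
#' equalization (per image), and a rigid rotation (within +/- 5 degrees) and
#' in-plane shift (within +/- 3 pixels) applied identically to both images
#' and to any ground-truth masks and deformation fields.
#'
#' @param pair list with `moving`, `fixed` (arrays or `image_volume`s),
#'   `brain_mask`, optionally `gt_mask` and `gt_field`.
#' @param probs named list of per-augmentation probabilities; omitted names
#'   default to 0 (off).
#' @param params named list of augmentation magnitudes.
#' @param seed optional seed.
#' @export
augment_pair <- function(pair,
                         probs = list(noise = 0, rotation = 0, shift = 0,
                                      brightness = 0, gradient = 0, ahe = 0),
                         params = list(noise_sd = 0.03, max_angle = 5,
                                       max_shift = 3, max_brightness = 0.1,
                                       max_gradient = 0.1),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  getp <- function(nm) if (is.null(probs[[nm]])) 0 else probs[[nm]]
  mov <- vol_values(pair$moving); fix <- vol_values(pair$fixed)
  brain <- pair$brain_mask
  d <- dim(mov)
  rng_ref <- diff(range(c(mov, fix)))
  per_image <- function(img) {
    if (runif(1) < getp("noise")) {
      img[brain] <- img[brain] + rnorm(sum(brain), sd = params$noise_sd * rng_ref)
    }
    if (runif(1) < getp("brightness")) {
      img[brain] <- img[brain] +
        runif(1, -params$max_brightness, params$max_brightness) * rng_ref
    }
    if (runif(1) < getp("gradient")) {
      dirang <- runif(1, 0, 2 * pi)
      ii <- (slice_index(d, 1) - (d[1] + 1) / 2) / d[1]
      jj <- (slice_index(d, 2) - (d[2] + 1) / 2) / d[2]
      ramp <- (cos(dirang) * ii + sin(dirang) * jj) *
        runif(1, -params$max_gradient, params$max_gradient) * 2 * rng_ref
      img[brain] <- img[brain] + ramp[brain]
    }
    if (runif(1) < getp("ahe")) {
      img <- vol_values(adaptive_hist_eq(img))
    }
    img
  }
  mov <- per_image(mov)
  fix <- per_image(fix)

  do_rot <- runif(1) < getp("rotation")
  do_shift <- runif(1) < getp("shift")
  if (do_rot || do_shift) {
    theta <- if (do_rot) runif(1, -params$max_angle, params$max_angle) else 0
    sh <- if (do_shift) runif(2, -params$max_shift, params$max_shift) else c(0, 0)
    rig <- rigid_sampling_field(d, theta, sh)
    mov <- cpp_warp(as.double(mov), as.integer(d), as.double(rig$u), 0L)
    fix <- cpp_warp(as.double(fix), as.integer(d), as.double(rig$u), 0L)
    brain <- array(cpp_warp(as.double(brain * 1), as.integer(d),
                            as.double(rig$u), 1L) > 0.5, d)
    if (!is.null(pair$gt_mask)) {
      pair$gt_mask <- array(cpp_warp(as.double(pair$gt_mask * 1),
                                     as.integer(d),
                                     as.double(rig$u), 1L) > 0.5, d)
    }
    if (!is.null(pair$gt_field)) {
      pair$gt_field <- transform_gt_field(pair$gt_field, rig)
    }
    pair$applied <- list(theta = theta, shift = sh)
  }
  pair$moving <- vol_like(array(mov, d), pair$moving)
  pair$fixed <- vol_like(array(fix, d), pair$fixed)
  pair$brain_mask <- brain
  pair
}

# index grid helper: array of coordinate `axis` values
slice_index <- function(d, axis) {
  slice.index(array(0, d), axis)
}
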