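#' Training objectives for joint registration and non-correspondence
#' segmentation
#'
#' The image distance is normalized cross-correlation, expressed as
#' `1 - NCC^2` so it is a minimizable quantity in `[0, 1]`. The default is a
#' local windowed NCC (window 9), the registration-community default that is
#' robust to smooth intensity bias; a global variant is available via
#' `window = "global"`.
#'
#' @name losses
NULL

LOSS_EPS <- 1e-5

#' Default loss weights
#'
#' `alpha` weighs the velocity smoothness penalty, `beta` the
#' non-correspondence regularizer (unsupervised objective) or the Dice term
#' (supervised objective), `gamma` the boundary term inside the
#' non-correspondence regularizer. `level_weights` are the deep-supervision
#' weights, finest level first, and must sum to one.
#'
#' @export
loss_weights <- function(alpha = 1, beta = 1, gamma = 1,
                         level_weights = c(0.7, 0.2, 0.1)) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, all(level_weights >= 0))
  if (abs(sum(level_weights) - 1) > 1e-8) {
    stop("`level_weights` must sum to 1")
  }
  list(alpha = alpha, beta = beta, gamma = gamma,
       level_weights = level_weights)
}

# Per-window NCC statistics via zero-padded box sums. Returns everything the
# value and the gradient formulas need.
ncc_stats <- function(fixed, moving, window, eps = LOSS_EPS) {
  d <- dim(fixed)
  ones <- array(1, dim = d)
  bx <- function(a) cpp_boxsum(as.double(a), as.integer(d), as.integer(window))
  n <- bx(ones)
  sF <- bx(fixed); sM <- bx(moving)
  sFF <- bx(fixed * fixed); sMM <- bx(moving * moving); sFM <- bx(fixed * moving)
  mF <- sF / n; mM <- sM / n
  cross <- sFM - sF * mM
  varF <- pmax(sFF - sF * mF, 0)
  varM <- pmax(sMM - sM * mM, 0)
  den <- varF * varM + eps
  ncc2 <- cross^2 / den
  list(d = d, n = n, mF = mF, mM = mM, cross = cross, varF = varF,
       varM = varM, den = den, ncc2 = ncc2)
}

#' Normalized cross-correlation distance
#'
#' `1 - NCC^2` averaged over local windows (or computed globally). Zero for
#' identical images and invariant to affine intensity rescaling within a
#' window; zero-variance windows are handled by an epsilon-stabilized
#' denominator and never produce NaN.
#'
#' @param fixed,moving images (`image_volume` or arrays) of equal shape.
#' @param window odd integer window edge length, or `"global"`.
#' @param eps stabilizer for the variance product.
#' @return Scalar in `[0, 1]`.
#' @export
ncc_distance <- function(fixed, moving, window = 9, eps = LOSS_EPS) {
  masked_distance(fixed, moving, N = NULL, window = window, eps = eps)
}

#' Masked image distance
#'
#' The per-window distance contribution is multiplied by `(1 - N)` before
#' averaging, so regions flagged as non-correspondent do not penalize the
#' registration.
#'
#' @param N non-correspondence map in `[0, 1]`, or `NULL` for no masking.
#' @inheritParams ncc_distance
#' @export
masked_distance <- function(fixed, moving, N = NULL, window = 9,
                            eps = LOSS_EPS) {
  fixed <- vol_values(fixed); moving <- vol_values(moving)
  if (!identical(dim(fixed), dim(moving))) {
    stop("`fixed` and `moving` must have the same shape")
  }
  if (!is.null(N)) {
    N <- vol_values(N)
    if (min(N) < 0 || max(N) > 1) stop("`N` must lie in [0, 1]")
    if (!identical(dim(N), dim(fixed))) stop("`N` shape mismatch")
  }
  w <- if (is.null(N)) 1 else (1 - N)
  if (identical(window, "global")) {
    st <- global_ncc_stats(fixed, moving, eps)
    return(mean(w * (1 - st$ncc2)))
  }
  if (window %% 2 != 1) stop("`window` must be odd")
  st <- ncc_stats(fixed, moving, window, eps)
  mean(w * (1 - st$ncc2))
}

global_ncc_stats <- function(fixed, moving, eps = LOSS_EPS) {
  mF <- mean(fixed); mM <- mean(moving)
  a <- fixed - mF; b <- moving - mM
  cross <- sum(a * b); varF <- sum(a * a); varM <- sum(b * b)
  den <- varF * varM + eps
  list(a = a, b = b, cross = cross, varF = varF, varM = varM, den = den,
       ncc2 = cross^2 / den)
}

# Gradient of mean(w * (1 - ncc2)) w.r.t. the moving image (and optionally
# the fixed image). `w` is a per-window-center weight grid or scalar 1.
masked_distance_grad_moving <- function(fixed, moving, N = NULL, window = 9,
                                        eps = LOSS_EPS) {
  fixed <- vol_values(fixed); moving <- vol_values(moving)
  d <- dim(fixed)
  nvox <- prod(d)
  w <- if (is.null(N)) array(1, d) else (1 - vol_values(N))
  if (identical(window, "global")) {
    st <- global_ncc_stats(fixed, moving, eps)
    # d ncc2 / dM_j = (2 cross a_j den - cross^2 varF 2 b_j) / den^2
    gn <- (2 * st$cross * st$a) / st$den -
      (2 * st$cross^2 * st$varF * st$b) / st$den^2
    dM <- -(sum(w) / nvox) * gn
    return(array(dM, d))
  }
  st <- ncc_stats(fixed, moving, window, eps)
  A <- w * (2 * st$cross / st$den)                 # -dL_c pre-factor on a_j
  B <- w * (-2 * st$cross^2 * st$varF / st$den^2)  # on b_j
  bx <- function(x) cpp_boxsum(as.double(x), as.integer(d), as.integer(window))
  dM <- fixed * bx(A) - bx(A * st$mF) + moving * bx(B) - bx(B * st$mM)
  array(-dM / nvox, d)
}

# Gradient of the masked distance w.r.t. N (the mask itself): -(1-ncc2)/nvox.
masked_distance_grad_N <- function(fixed, moving, window = 9,
                                   eps = LOSS_EPS) {
  fixed <- vol_values(fixed); moving <- vol_values(moving)
  d <- dim(fixed)
  if (identical(window, "global")) {
    st <- global_ncc_stats(fixed, moving, eps)
    return(array(-(1 - st$ncc2) / prod(d), d))
  }
  st <- ncc_stats(fixed, moving, window, eps)
  array(-(1 - st$ncc2) / prod(d), d)
}

#' Velocity smoothness penalty
#'
#' Mean over voxels, components and axes of squared finite-difference
#' gradients of the velocity field; homogeneous of degree two.
#'
#' @param v velocity field.
#' @export
smoothness_reg <- function(v) {
  nd <- field_ndim(v)
  total <- 0
  count <- 0
  for (k in seq_len(nd)) {
    g <- spatial_gradient(field_component(v, k))
    total <- total + sum(g * g)
    count <- count + length(g)
  }
  total / count
}

smoothness_reg_grad <- function(v) {
  nd <- field_ndim(v)
  count <- prod(field_spatial_dim(v)) * nd * nd
  out <- v * 0
  for (k in seq_len(nd)) {
    comp <- field_component(v, k)
    acc <- comp * 0
    for (ax in seq_len(nd)) {
      acc <- acc + diff_axis_adjoint(diff_axis(comp, ax), ax)
    }
    field_component(out, k) <- 2 * acc / count
  }
  out
}

#' Non-correspondence regularizer
#'
#' Area term (mean of `N`) plus `gamma` times a bounded boundary term:
#' by default `tanh` of the RMS gradient magnitude of `N`; with
#' `per_voxel = TRUE`, the mean over voxels of `tanh` of the local gradient
#' magnitude. Favours small, regularly bordered segmentations. The area
#' term uses the mean rather than the sum so the weight is scale-free
#' across image sizes.
#'
#' @param N non-correspondence map in `[0, 1]`.
#' @param gamma boundary-term weight.
#' @param per_voxel apply `tanh` per voxel instead of to the global norm.
#' @export
noncorr_reg <- function(N, gamma = 1, per_voxel = FALSE) {
  N <- vol_values(N)
  g <- spatial_gradient(N)
  d <- dim(N)
  if (per_voxel) {
    nd <- length(d)
    mag <- sqrt(Reduce(`+`, lapply(seq_len(nd), function(ax) {
      (if (nd == 2L) g[, , ax] else g[, , , ax])^2
    })))
    return(mean(N) + gamma * mean(tanh(mag)))
  }
  r <- sqrt(mean(g * g))
  mean(N) + gamma * tanh(r)
}

noncorr_reg_grad <- function(N, gamma = 1, per_voxel = FALSE) {
  N <- vol_values(N)
  d <- dim(N)
  nd <- length(d)
  g <- spatial_gradient(N)
  gax <- function(ax) if (nd == 2L) g[, , ax] else g[, , , ax]
  out <- array(1 / prod(d), d)
  if (per_voxel) {
    mag <- sqrt(Reduce(`+`, lapply(seq_len(nd), function(ax) gax(ax)^2)))
    sech2 <- 1 - tanh(mag)^2
    for (ax in seq_len(nd)) {
      out <- out + gamma *
        diff_axis_adjoint(sech2 * gax(ax) / pmax(mag, 1e-12), ax) / prod(d)
    }
    return(out)
  }
  r <- sqrt(mean(g * g))
  if (r > 1e-12) {
    acc <- N * 0
    for (ax in seq_len(nd)) {
      acc <- acc + diff_axis_adjoint(gax(ax), ax)
    }
    out <- out + gamma * (1 - tanh(r)^2) * acc / (r * length(g))
  }
  out
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`; zero for a perfect
#' binary prediction and, by the epsilon convention, for the empty-vs-empty
#' case.
#'
#' @param pred soft prediction in `[0, 1]`.
#' @param target binary grid of the same shape.
#' @export
dice_loss <- function(pred, target, eps = LOSS_EPS) {
  pred <- vol_values(pred); target <- vol_values(target)
  if (!identical(dim(pred), dim(target))) stop("shape mismatch in dice_loss")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

dice_loss_grad <- function(pred, target, eps = LOSS_EPS) {
  pred <- vol_values(pred); target <- vol_values(target)
  den <- sum(pred) + sum(target) + eps
  num <- 2 * sum(pred * target) + eps
  -(2 * target * den - num) / den^2
}

#' Deep-supervision weighting
#'
#' Weighted sum of per-level losses, finest level first; the default weights
#' `(0.7, 0.2, 0.1)` give the finest resolution the highest weight.
#'
#' @param losses_per_level numeric vector of per-level losses.
#' @param level_weights matching weight vector.
#' @export
deep_supervision <- function(losses_per_level,
                             level_weights = c(0.7, 0.2, 0.1)) {
  if (length(losses_per_level) != length(level_weights)) {
    stop("number of losses and level weights differ")
  }
  sum(losses_per_level * level_weights)
}

#' Unsupervised joint objective
#'
#' Masked NCC distance between follow-up and the warped baseline, plus
#' `alpha` times the velocity smoothness penalty and `beta` times the
#' non-correspondence regularizer. No ground truth is needed: the
#' non-correspondence map is found as the outlier region of the image
#' distance.
#'
#' @param F_img,B_img follow-up / baseline.
#' @param v velocity field; the deformation is `svf_exp(v)`.
#' @param N non-correspondence map in `[0, 1]`.
#' @param weights see [loss_weights()].
#' @param window NCC window.
#' @param steps squaring steps for the exponential.
#' @export
eq_noncorr_loss <- function(F_img, B_img, v, N, weights = loss_weights(),
                            window = 9, steps = 7L) {
  phi <- svf_exp(v, steps)
  warped <- warp_image(vol_values(B_img), phi)
  masked_distance(F_img, warped, N, window) +
    weights$alpha * smoothness_reg(v) +
    weights$beta * noncorr_reg(N, weights$gamma)
}

eq_noncorr_grad <- function(F_img, B_img, v, N, weights = loss_weights(),
                            window = 9, steps = 7L) {
  Fv <- vol_values(F_img); Bv <- vol_values(B_img)
  tape <- svf_exp_with_tape(v, steps)
  phi <- tape$phi
  warped <- warp_image(Bv, phi)
  g_warped <- masked_distance_grad_moving(Fv, warped, N, window)
  wv <- warp_vjp(Bv, phi, g_warped)
  dv <- svf_exp_vjp(tape, wv$d_phi) + weights$alpha * smoothness_reg_grad(v)
  dN <- masked_distance_grad_N(Fv, warped, window) +
    weights$beta * noncorr_reg_grad(N, weights$gamma)
  list(dv = dv, dN = dN)
}

#' Supervised appearance-adaptation objective
#'
#' NCC distance between the follow-up and the appearance-adapted, deformed
#' baseline `(B + N * A) o phi`, plus `alpha` times the velocity smoothness
#' penalty and `beta` times the Dice loss between the warped
#' non-correspondence map and the ground-truth new-lesion segmentation.
#' Appearance offsets are masked with `N`, so intensity is synthesized only
#' inside non-correspondent regions.
#'
#' @param A appearance-offset map (image intensity units).
#' @param S binary ground-truth segmentation.
#' @param order `"adapt_then_deform"` composes the appearance change before
#'   the deformation; `"deform_then_add"` deforms baseline and masked offsets
#'   separately and sums them.
#' @inheritParams eq_noncorr_loss
#' @export
eq_appearance_loss <- function(F_img, B_img, v, N, A, S,
                               weights = loss_weights(), window = 9,
                               steps = 7L,
                               order = c("adapt_then_deform",
                                         "deform_then_add")) {
  order <- match.arg(order)
  Fv <- vol_values(F_img); Bv <- vol_values(B_img)
  Nv <- vol_values(N); Av <- vol_values(A)
  phi <- svf_exp(v, steps)
  adapted <- if (order == "adapt_then_deform") {
    warp_image(Bv + Nv * Av, phi)
  } else {
    warp_image(Bv, phi) + warp_image(Nv * Av, phi)
  }
  warped_N <- warp_image(Nv, phi)
  ncc_distance(Fv, adapted, window) +
    weights$alpha * smoothness_reg(v) +
    weights$beta * dice_loss(warped_N, S)
}

eq_appearance_grad <- function(F_img, B_img, v, N, A, S,
                               weights = loss_weights(), window = 9,
                               steps = 7L,
                               order = c("adapt_then_deform",
                                         "deform_then_add")) {
  order <- match.arg(order)
  Fv <- vol_values(F_img); Bv <- vol_values(B_img)
  Nv <- vol_values(N); Av <- vol_values(A); Sv <- vol_values(S)
  tape <- svf_exp_with_tape(v, steps)
  phi <- tape$phi
  M <- Bv + Nv * Av
  if (order == "adapt_then_deform") {
    adapted <- warp_image(M, phi)
  } else {
    adapted <- warp_image(Bv, phi) + warp_image(Nv * Av, phi)
  }
  warped_N <- warp_image(Nv, phi)

  g_adapted <- masked_distance_grad_moving(Fv, adapted, NULL, window)
  g_wN <- weights$beta * dice_loss_grad(warped_N, Sv)

  d_phi_total <- phi * 0
  if (order == "adapt_then_deform") {
    wv <- warp_vjp(M, phi, g_adapted)
    dM <- wv$d_img
    d_phi_total <- d_phi_total + wv$d_phi
    dB <- dM
    dN_dist <- dM * Av
    dA <- dM * Nv
  } else {
    wv1 <- warp_vjp(Bv, phi, g_adapted)
    wv2 <- warp_vjp(Nv * Av, phi, g_adapted)
    dB <- wv1$d_img
    dN_dist <- wv2$d_img * Av
    dA <- wv2$d_img * Nv
    d_phi_total <- d_phi_total + wv1$d_phi + wv2$d_phi
  }
  wvN <- warp_vjp(Nv, phi, g_wN)
  d_phi_total <- d_phi_total + wvN$d_phi
  dN <- dN_dist + wvN$d_img

  dv <- svf_exp_vjp(tape, d_phi_total) +
    weights$alpha * smoothness_reg_grad(v)
  list(dv = dv, dN = dN, dA = dA, dB = dB)
}

#' Pre-training loss
#'
#' Supervised loss for simulated pairs: Dice between the predicted
#' non-correspondence map and the simulated lesion mask, plus mean squared
#' error between the predicted deformation (`svf_exp` of the predicted
#' velocity) and the known simulated deformation.
#'
#' @param pred_v predicted velocity field.
#' @param gt_phi ground-truth deformation field.
#' @param pred_N predicted non-correspondence map.
#' @param gt_S binary simulated lesion mask.
#' @param steps squaring steps.
#' @details The deformation error is the mean over voxels of the squared
#'   Euclidean norm of the displacement difference, so a wrongly predicted
#'   translation by `c` voxels contributes `c^2`.
#' @export
pretrain_loss <- function(pred_v, gt_phi, pred_N, gt_S, steps = 7L) {
  phi <- svf_exp(pred_v, steps)
  nvox <- prod(field_spatial_dim(phi))
  dice_loss(pred_N, gt_S) + sum((phi - gt_phi)^2) / nvox
}

pretrain_grad <- function(pred_v, gt_phi, pred_N, gt_S, steps = 7L) {
  tape <- svf_exp_with_tape(pred_v, steps)
  phi <- tape$phi
  nvox <- prod(field_spatial_dim(phi))
  g_phi <- 2 * (phi - gt_phi) / nvox
  list(dv = svf_exp_vjp(tape, g_phi),
       dN = dice_loss_grad(pred_N, gt_S),
       loss = dice_loss(pred_N, gt_S) + sum((phi - gt_phi)^2) / nvox)
}
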