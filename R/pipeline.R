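#' Training and inference pipeline
#'
#' Training has two phases. Pre-training counters the class imbalance of new
#' lesions: simulated lesions are inserted on the fly into lesion-free
#' baselines, a random in-plane elastic deformation produces the fixed image,
#' and the network is supervised with Dice loss on the simulated lesion mask
#' plus mean squared error on the known deformation. Fine-tuning then uses
#' the appearance-adaptation objective on slabs that contain real (or, for
#' phantoms, cohort ground-truth) new lesions, each slab passed twice: once
#' as is and once flipped horizontally. Both phases are deeply supervised on
#' three resolutions with weights 0.7 / 0.2 / 0.1.
#'
#' @name pipeline
NULL

#' Training configuration
#'
#' Defaults reflect the full-scale training protocol: pre-training for 200 epochs with
#' Adam at learning rate 1e-4 decayed by 0.8 every 20th epoch; fine-tuning
#' for 400 epochs with an exponentially decaying learning rate starting at
#' 1e-4.
#'
#' @param phase `"pretrain"` or `"finetune"`.
#' @param epochs number of epochs (defaults: 200 pre-train, 400 fine-tune).
#' @param lr_init initial learning rate.
#' @param lr_decay decay factor (0.8 per 20-epoch step for pre-training;
#'   per-epoch exponential factor for fine-tuning).
#' @param lr_step epochs between step decays (pre-training).
#' @param slabs_per_case training slabs sampled per case per epoch.
#' @param folds cross-validation folds.
#' @param seed RNG seed for sampling and augmentation.
#' @param steps scaling-and-squaring steps during training.
#' @param window NCC window for the fine-tuning objective.
#' @param weights [loss_weights()].
#' @param augment named list of augmentation probabilities (see
#'   [augment_pair()]); `NULL` disables augmentation.
#' @param seg_stabilizer weight of a positively-weighted cross-entropy term
#'   on the segmentation logits added during training. Plain Dice loss under
#'   extreme class imbalance can collapse to the all-background plateau
#'   (the sigmoid saturates and gradients vanish); the logit-space
#'   cross-entropy gradient does not vanish and prevents that. Set to 0 to
#'   train on the bare objective.
#' @param p_negative fraction of pre-training slabs left lesion-free
#'   (deformation-only negatives that teach false-positive suppression).
#' @export
train_config <- function(phase = c("pretrain", "finetune"), epochs = NULL,
                         lr_init = 1e-4, lr_decay = NULL, lr_step = 20L,
                         slabs_per_case = 4L, folds = 5L, seed = 1L,
                         steps = 5L, window = 9L,
                         weights = loss_weights(), augment = NULL,
                         seg_stabilizer = 1, p_negative = 0.25) {
  phase <- match.arg(phase)
  if (is.null(epochs)) epochs <- if (phase == "pretrain") 200L else 400L
  if (is.null(lr_decay)) lr_decay <- if (phase == "pretrain") 0.8 else 0.995
  structure(list(phase = phase, epochs = as.integer(epochs),
                 lr_init = lr_init, lr_decay = lr_decay,
                 lr_step = as.integer(lr_step),
                 slabs_per_case = as.integer(slabs_per_case),
                 folds = as.integer(folds), seed = as.integer(seed),
                 steps = as.integer(steps), window = window,
                 weights = weights, augment = augment,
                 seg_stabilizer = seg_stabilizer, p_negative = p_negative),
            class = "train_config")
}

# Positively-weighted binary cross-entropy on the segmentation logits.
# Returns the gradient in logit space, (N - t) * w / sum(w), which stays
# informative when the sigmoid saturates; `value` is the matching loss.
bce_logit <- function(N, target, pos_weight = NULL, cap = 50) {
  w <- array(1, dim(N))
  n_fg <- sum(target > 0)
  if (is.null(pos_weight)) {
    pos_weight <- if (n_fg > 0) min((length(target) - n_fg) / n_fg, cap) else 1
  }
  w[target > 0] <- pos_weight
  Nc <- pmin(pmax(N, 1e-7), 1 - 1e-7)
  val <- sum(w * (-(target * log(Nc) + (1 - target) * log(1 - Nc)))) / sum(w)
  list(grad_z = (N - target) * w / sum(w), value = val)
}

#' Learning rate at a given epoch
#'
#' Pre-training: step decay, `lr_init * decay^floor(epoch / step)`.
#' Fine-tuning: exponential, `lr_init * decay^(epoch - 1)`.
#' @param cfg [train_config()]; `epoch` 1-based epoch number.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (cfg$phase == "pretrain") {
    cfg$lr_init * cfg$lr_decay^(epoch %/% cfg$lr_step)
  } else {
    cfg$lr_init * cfg$lr_decay^(epoch - 1)
  }
}

# ---------------------------------------------------------------------------
# Slab helpers
# ---------------------------------------------------------------------------

# 5-slice (generally in_slices) slab centred on slice k, replicating edge
# slices beyond the volume ends.
get_slab <- function(vals, k, n_slices) {
  d <- dim(vals)
  h <- (n_slices - 1L) %/% 2L
  ks <- pmin(pmax(seq(k - h, k + h), 1L), d[3])
  vals[, , ks, drop = FALSE]
}

downsample2 <- function(x) {
  d <- dim(x)
  (x[seq(1, d[1], 2), seq(1, d[2], 2)] +
     x[seq(2, d[1], 2), seq(1, d[2], 2)] +
     x[seq(1, d[1], 2), seq(2, d[2], 2)] +
     x[seq(2, d[1], 2), seq(2, d[2], 2)]) / 4
}

image_pyramid <- function(x, levels) {
  out <- vector("list", levels)
  out[[1]] <- x
  for (l in seq_len(levels - 1L)) out[[l + 1L]] <- downsample2(out[[l]])
  out
}

mask_pyramid <- function(m, levels) {
  p <- image_pyramid(m * 1, levels)
  lapply(p, function(x) (x > 0) * 1)
}

field_pyramid_2d <- function(u, levels) {
  out <- vector("list", levels)
  out[[1]] <- u
  for (l in seq_len(levels - 1L)) {
    prev <- out[[l]]
    nxt <- array(0, dim = c(dim(prev)[1] / 2, dim(prev)[2] / 2, 2))
    nxt[, , 1] <- downsample2(prev[, , 1]) / 2
    nxt[, , 2] <- downsample2(prev[, , 2]) / 2
    out[[l + 1L]] <- nxt
  }
  out
}

elastic_field_2d <- function(d2, amplitude, smoothing) {
  u <- array(0, dim = c(d2, 2))
  if (amplitude > 0) {
    u[, , 1] <- gaussian_smooth(array(rnorm(prod(d2)), d2), smoothing)
    u[, , 2] <- gaussian_smooth(array(rnorm(prod(d2)), d2), smoothing)
    mag <- sqrt(u[, , 1]^2 + u[, , 2]^2)
    if (max(mag) > 0) u <- u * (amplitude / max(mag))
  }
  u
}

warp_slab_2d <- function(slab, u2, mode = "linear") {
  d <- dim(slab)
  out <- slab
  for (s in seq_len(d[3])) {
    out[, , s] <- cpp_warp(as.double(slab[, , s]), as.integer(d[1:2]),
                           as.double(u2), if (mode == "nearest") 1L else 0L)
  }
  out
}

flip_w <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) x[, rev(seq_len(d[2]))]
  else x[, rev(seq_len(d[2])), , drop = FALSE]
}

# One on-the-fly pre-training sample: slab from a lesion-free baseline,
# simulated lesions, in-plane elastic deformation, optional augmentation.
make_pretrain_sample <- function(case, n_slices, k, elastic_amplitude = 3,
                                 elastic_smoothing = 8, augment = NULL,
                                 lesion_params = list(), insert = TRUE) {
  B <- vol_values(case$baseline)
  mov <- get_slab(B, k, n_slices)
  central <- (n_slices + 1L) %/% 2L
  if (insert) {
    cand <- get_slab(case$candidate * 1, k, n_slices) > 0
    # draw lesion centres on the central slice so the supervised target of
    # the slab is informative (the ellipsoid support still spans slices)
    cand_c <- cand & (slice_index(dim(cand), 3) == central)
    if (!any(cand_c)) cand_c <- cand
    ins <- do.call(insert_lesions, c(list(img = mov, cand = cand_c),
                                     lesion_params))
  } else {
    # lesion-free negative: the pair differs by deformation only
    ins <- list(image = mov, mask = array(FALSE, dim(mov)))
  }
  u2 <- elastic_field_2d(dim(mov)[1:2], elastic_amplitude, elastic_smoothing)
  fixed <- warp_slab_2d(ins$image, u2)
  gt_mask <- array(cpp_warp(as.double(ins$mask[, , central] * 1),
                            as.integer(dim(mov)[1:2]), as.double(u2), 1L) > 0.5,
                   dim(mov)[1:2])
  smp <- list(moving = mov, fixed = fixed, gt_mask = gt_mask * 1,
              gt_field = u2)
  if (!is.null(augment)) {
    smp <- augment_slab_sample(smp, get_slab(case$brain_mask * 1, k,
                                             n_slices) > 0, augment)
  }
  smp
}

# Intensity and rigid augmentation on a slab sample, keeping ground truths
# consistent (the rigid part is in-plane and shared between both slabs).
augment_slab_sample <- function(smp, brain_slab, probs,
                                params = list(noise_sd = 0.02, max_angle = 5,
                                              max_shift = 3,
                                              max_brightness = 0.1,
                                              max_gradient = 0.1)) {
  getp <- function(nm) if (is.null(probs[[nm]])) 0 else probs[[nm]]
  d <- dim(smp$moving)
  rng_ref <- diff(range(c(smp$moving, smp$fixed)))
  per_image <- function(img) {
    if (runif(1) < getp("noise")) {
      img[brain_slab] <- img[brain_slab] +
        rnorm(sum(brain_slab), sd = params$noise_sd * rng_ref)
    }
    if (runif(1) < getp("brightness")) {
      img[brain_slab] <- img[brain_slab] +
        runif(1, -params$max_brightness, params$max_brightness) * rng_ref
    }
    if (runif(1) < getp("ahe")) img <- vol_values(adaptive_hist_eq(img))
    img
  }
  smp$moving <- per_image(smp$moving)
  smp$fixed <- per_image(smp$fixed)
  do_rot <- runif(1) < getp("rotation")
  do_shift <- runif(1) < getp("shift")
  if (do_rot || do_shift) {
    theta <- if (do_rot) runif(1, -params$max_angle, params$max_angle) else 0
    sh <- if (do_shift) runif(2, -params$max_shift, params$max_shift) else c(0, 0)
    rig <- rigid_sampling_field(d[1:2], theta, sh)
    smp$moving <- warp_slab_2d(smp$moving, rig$u)
    smp$fixed <- warp_slab_2d(smp$fixed, rig$u)
    smp$gt_mask <- (cpp_warp(as.double(smp$gt_mask), as.integer(d[1:2]),
                             as.double(rig$u), 1L) > 0.5) * 1
    if (!is.null(smp$gt_field)) {
      smp$gt_field <- transform_gt_field(smp$gt_field, rig)
    }
  }
  smp
}

# ---------------------------------------------------------------------------
# Training loops
# ---------------------------------------------------------------------------

#' Pre-train on simulated lesions
#'
#' @param model a built network.
#' @param cohort list of cases (see [make_longitudinal_case()] /
#'   [read_cohort()]); their baselines must be lesion-free.
#' @param cfg a `pretrain` [train_config()].
#' @param verbose print per-epoch loss.
#' @return List with `model` and `history` (per-epoch mean loss and lr).
#' @export
pretrain <- function(model, cohort, cfg = train_config("pretrain"),
                     verbose = FALSE) {
  stopifnot(cfg$phase == "pretrain")
  set.seed(cfg$seed)
  n_slices <- model$cfg$in_slices
  lw <- cfg$weights$level_weights
  state <- adam_init(model$params)
  # slices with candidate voxels, per case
  valid <- lapply(cohort, function(cs) {
    which(apply(cs$candidate, 3, any))
  })
  hist_loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, ep)
    ep_losses <- c()
    for (ci in seq_along(cohort)) {
      if (length(valid[[ci]]) == 0) next
      ks <- sample(valid[[ci]], cfg$slabs_per_case, replace = TRUE)
      for (k in ks) {
        smp <- make_pretrain_sample(cohort[[ci]], n_slices, k,
                                    augment = cfg$augment,
                                    insert = runif(1) >= cfg$p_negative)
        fwd <- net_forward(model, smp$moving, smp$fixed, train = TRUE)
        mp <- mask_pyramid(smp$gt_mask, model$cfg$out_levels)
        fp <- field_pyramid_2d(smp$gt_field, model$cfg$out_levels)
        lgrads <- vector("list", model$cfg$out_levels)
        loss <- 0
        for (lv in seq_len(model$cfg$out_levels)) {
          out <- fwd$levels[[lv]]
          pg <- pretrain_grad(out$v, fp[[lv]], out$N, mp[[lv]],
                              steps = cfg$steps)
          lgrads[[lv]] <- list(dv = lw[lv] * pg$dv, dN = lw[lv] * pg$dN,
                               dA = NULL)
          lvloss <- pg$loss
          if (cfg$seg_stabilizer > 0) {
            bce <- bce_logit(out$N, mp[[lv]])
            lgrads[[lv]]$dzN <- lw[lv] * cfg$seg_stabilizer * bce$grad_z
            lvloss <- lvloss + cfg$seg_stabilizer * bce$value
          }
          loss <- loss + lw[lv] * lvloss
        }
        if (!is.finite(loss)) {
          stop(sprintf("pre-training diverged (case %d, slice %d, epoch %d)",
                       ci, k, ep))
        }
        grads <- net_backward(model, fwd, lgrads)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
        ep_losses <- c(ep_losses, loss)
      }
    }
    hist_loss[ep] <- mean(ep_losses)
    if (verbose) message(sprintf("pretrain epoch %d loss %.4f lr %.2e",
                                 ep, hist_loss[ep], lr))
  }
  list(model = model,
       history = data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss,
                            lr = vapply(seq_len(cfg$epochs),
                                        function(e) lr_at_epoch(cfg, e),
                                        numeric(1))))
}

#' Fine-tune with the appearance-adaptation objective
#'
#' Batches are drawn only from slabs whose central slice intersects the
#' ground-truth lesion mask; each slab is passed twice, once in the original
#' orientation and once flipped horizontally.
#'
#' @inheritParams pretrain
#' @param cfg a `finetune` [train_config()].
#' @param validation optional indices of held-out cases; every `val_every`
#'   epochs the mean lesion-level F1 on them is computed and the checkpoint
#'   with the best validation score is returned (validation-based model
#'   selection within a cross-validation fold).
#' @param val_every epochs between validation evaluations.
#' @export
finetune <- function(model, cohort, cfg = train_config("finetune"),
                     verbose = FALSE, validation = NULL, val_every = 5L) {
  stopifnot(cfg$phase == "finetune")
  set.seed(cfg$seed)
  n_slices <- model$cfg$in_slices
  lw <- cfg$weights$level_weights
  state <- adam_init(model$params)
  lesion_slices <- lapply(cohort, function(cs) {
    which(apply(cs$gt_lesion_mask, 3, any))
  })
  usable <- setdiff(which(vapply(lesion_slices, length, integer(1)) > 0),
                    validation)
  if (length(usable) == 0) {
    stop("no slabs intersect the ground-truth lesion masks")
  }
  # validation score: mean lesion-level F1 over lesioned validation cases,
  # with an explicit penalty on false lesions so checkpoints that drift
  # toward over-segmentation are not selected
  val_score <- function(m) {
    f1s <- c(); fps <- c()
    for (ci in validation) {
      cs <- cohort[[ci]]
      seg <- segment_volume(m, cs$baseline, cs$follow_up)
      post <- postprocess(seg$seg, cs$brain_mask, cs$baseline$spacing)
      dm <- detection_metrics(post, cs$gt_lesion_mask * 1,
                              cs$baseline$spacing)
      if (!is.na(dm$f1)) f1s <- c(f1s, dm$f1)
      fps <- c(fps, dm$fp_count)
    }
    (if (length(f1s) > 0) mean(f1s) else 0) - 0.1 * mean(fps)
  }
  best <- if (is.null(validation)) {
    list(score = -Inf, params = model$params)
  } else {
    # the incoming (epoch-0) checkpoint competes too
    list(score = val_score(model), params = model$params)
  }
  hist_loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, ep)
    ep_losses <- c()
    for (ci in usable) {
      cs <- cohort[[ci]]
      B <- vol_values(cs$baseline)
      F_ <- vol_values(cs$follow_up)
      ks <- sample(lesion_slices[[ci]],
                   min(cfg$slabs_per_case, length(lesion_slices[[ci]])))
      for (k in ks) {
        Bs <- get_slab(B, k, n_slices)
        Fs <- get_slab(F_, k, n_slices)
        S2 <- cs$gt_lesion_mask[, , k] * 1
        for (flip in c(FALSE, TRUE)) {
          Bsl <- if (flip) flip_w(Bs) else Bs
          Fsl <- if (flip) flip_w(Fs) else Fs
          Ssl <- if (flip) flip_w(S2) else S2
          central <- (n_slices + 1L) %/% 2L
          Bp <- image_pyramid(Bsl[, , central], model$cfg$out_levels)
          Fp <- image_pyramid(Fsl[, , central], model$cfg$out_levels)
          Sp <- mask_pyramid(Ssl, model$cfg$out_levels)
          fwd <- net_forward(model, Bsl, Fsl, train = TRUE)
          lgrads <- vector("list", model$cfg$out_levels)
          loss <- 0
          for (lv in seq_len(model$cfg$out_levels)) {
            out <- fwd$levels[[lv]]
            gl <- eq_appearance_grad(Fp[[lv]], Bp[[lv]], out$v, out$N, out$A,
                                     Sp[[lv]], cfg$weights, cfg$window,
                                     cfg$steps)
            ll <- eq_appearance_loss(Fp[[lv]], Bp[[lv]], out$v, out$N, out$A,
                                     Sp[[lv]], cfg$weights, cfg$window,
                                     cfg$steps)
            lgrads[[lv]] <- list(dv = lw[lv] * gl$dv, dN = lw[lv] * gl$dN,
                                 dA = lw[lv] * gl$dA)
            if (cfg$seg_stabilizer > 0) {
              bce <- bce_logit(out$N, Sp[[lv]])
              lgrads[[lv]]$dzN <- lw[lv] * cfg$seg_stabilizer * bce$grad_z
              ll <- ll + cfg$seg_stabilizer * bce$value
            }
            loss <- loss + lw[lv] * ll
          }
          if (!is.finite(loss)) {
            stop(sprintf("fine-tuning diverged (case %d, slice %d, epoch %d)",
                         ci, k, ep))
          }
          grads <- net_backward(model, fwd, lgrads)
          upd <- adam_step(model$params, grads, state, lr)
          model$params <- upd$params
          state <- upd$state
          ep_losses <- c(ep_losses, loss)
        }
      }
    }
    hist_loss[ep] <- mean(ep_losses)
    if (!is.null(validation) &&
        (ep %% val_every == 0 || ep == cfg$epochs)) {
      sc <- val_score(model)
      if (sc > best$score) best <- list(score = sc, params = model$params)
      if (verbose) message(sprintf("  validation score %.4f", sc))
    }
    if (verbose) message(sprintf("finetune epoch %d loss %.4f lr %.2e",
                                 ep, hist_loss[ep], lr))
  }
  if (!is.null(validation)) model$params <- best$params
  list(model = model,
       history = data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss))
}

# ---------------------------------------------------------------------------
# Inference
# ---------------------------------------------------------------------------

#' Segment a volume pair slice-wise
#'
#' Iterates axially through the co-registered volumes, feeding the slab
#' centred on each slice and keeping the central-slice non-correspondence
#' map, appearance offsets and deformation at full resolution. With several
#' models the binarized segmentations are combined by per-voxel majority
#' vote (ties broken positive).
#'
#' @param models one model or a list of models (e.g. the fold models of a
#'   cross-validation).
#' @param B,F_img baseline / follow-up (`image_volume` or array), rigidly
#'   pre-aligned, isotropically resampled.
#' @param threshold binarization threshold on `N` (default 0.5).
#' @param votes_required votes needed for a positive voxel (default: strict
#'   majority, ties positive).
#' @return List with `seg` (binary volume), `prob` (mean `N`), `appearance`
#'   (mean `A`), `deformation` (`(H, W, 2, D)` per-slice in-plane fields,
#'   mean across members), `member_segs`.
#' @export
segment_volume <- function(models, B, F_img, threshold = 0.5,
                           votes_required = NULL) {
  if (inherits(models, "noncorr_net")) models <- list(models)
  Bv <- vol_values(B); Fv <- vol_values(F_img)
  if (!identical(dim(Bv), dim(Fv))) stop("volume shapes differ")
  d <- dim(Bv)
  n_slices <- models[[1]]$cfg$in_slices
  if (d[3] < n_slices) {
    stop(sprintf("volume has %d slices; at least %d required", d[3], n_slices))
  }
  m <- length(models)
  if (is.null(votes_required)) votes_required <- ceiling(m / 2)
  probs <- vector("list", m)
  apps <- vector("list", m)
  defs <- vector("list", m)
  for (mi in seq_len(m)) {
    prob <- array(0, d)
    app <- array(0, d)
    def <- array(0, dim = c(d[1], d[2], 2, d[3]))
    for (k in seq_len(d[3])) {
      fwd <- net_forward(models[[mi]], get_slab(Bv, k, n_slices),
                         get_slab(Fv, k, n_slices))
      out <- fwd$levels[[1]]
      prob[, , k] <- out$N
      app[, , k] <- out$A
      def[, , , k] <- svf_exp(out$v)
    }
    probs[[mi]] <- prob
    apps[[mi]] <- app
    defs[[mi]] <- def
  }
  member_segs <- lapply(probs, function(p) p >= threshold)
  list(seg = majority_vote(member_segs, votes_required),
       prob = Reduce(`+`, probs) / m,
       appearance = Reduce(`+`, apps) / m,
       deformation = Reduce(`+`, defs) / m,
       member_segs = member_segs)
}

#' Majority vote over ensemble member segmentations
#'
#' A voxel is positive iff at least `votes_required` members mark it. The
#' default is a strict majority with ties (even member counts) broken
#' positive.
#'
#' @param member_segs list of binary volumes on a common grid.
#' @param votes_required votes needed for a positive voxel.
#' @export
majority_vote <- function(member_segs, votes_required = NULL) {
  m <- length(member_segs)
  if (is.null(votes_required)) votes_required <- ceiling(m / 2)
  votes <- Reduce(`+`, lapply(member_segs, function(s) vol_values(s) * 1))
  votes >= votes_required
}

#' Post-process a segmentation
#'
#' Multiplies by the brain mask, labels 26-connected components and removes
#' every lesion strictly smaller than `min_vol_mm3` (3 mm^3 by default; a
#' 3 mm^3 lesion at 1 mm isotropic spacing is kept). Idempotent.
#'
#' @param seg binary volume.
#' @param brain_mask optional binary mask.
#' @param spacing voxel size in mm.
#' @param min_vol_mm3 minimum lesion volume to keep.
#' @export
postprocess <- function(seg, brain_mask = NULL,
                        spacing = rep(1, length(dim(vol_values(seg)))),
                        min_vol_mm3 = 3) {
  seg <- vol_values(seg) > 0
  if (!is.null(brain_mask)) seg <- seg & (vol_values(brain_mask) > 0)
  lab <- label_lesions(seg, spacing)
  if (lab$count == 0) return(seg)
  keep <- which(lab$volumes_mm3 >= min_vol_mm3)
  array(lab$labels %in% keep, dim(seg))
}

#' Model new lesions on the baseline
#'
#' Adds the appearance offsets, masked with the non-correspondence
#' segmentation, to the baseline and deforms the adapted baseline to match
#' the follow-up. `"adapt_then_deform"` composes appearance before the
#' deformation; `"deform_then_add"` deforms baseline and masked offsets
#' separately and sums them.
#'
#' @param B,F_img baseline / follow-up, 2-D arrays or 3-D volumes.
#' @param N,A non-correspondence map / appearance offsets.
#' @param phi deformation: `(H, W, 2)` for 2-D input or `(H, W, 2, D)`
#'   per-slice fields for 3-D input.
#' @param order composition order.
#' @return List with `adapted`, `diff_baseline` (`F - B`) and
#'   `diff_adapted` (`F - adapted`).
#' @export
model_lesions <- function(B, F_img, N, A, phi,
                          order = c("adapt_then_deform", "deform_then_add")) {
  order <- match.arg(order)
  Bv <- vol_values(B); Fv <- vol_values(F_img)
  Nv <- vol_values(N); Av <- vol_values(A)
  d <- dim(Bv)
  apply_phi <- function(img) {
    if (length(d) == 2L) {
      warp_image(img, phi)
    } else {
      out <- img
      for (k in seq_len(d[3])) {
        out[, , k] <- cpp_warp(as.double(img[, , k]), as.integer(d[1:2]),
                               as.double(phi[, , , k]), 0L)
      }
      out
    }
  }
  adapted <- if (order == "adapt_then_deform") {
    apply_phi(Bv + Nv * Av)
  } else {
    apply_phi(Bv) + apply_phi(Nv * Av)
  }
  list(adapted = adapted, diff_baseline = Fv - Bv,
       diff_adapted = Fv - adapted)
}

#' Cross-validation fold assignment
#'
#' Disjoint validation folds of near-equal size covering the cohort,
#' deterministic for a seed.
#'
#' @param n number of cases (or a cohort list).
#' @param folds number of folds; `seed` RNG seed.
#' @return Integer vector of fold labels (1..folds), one per case.
#' @export
crossval_split <- function(n, folds = 5L, seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (folds < 2) stop("`folds` must be >= 2")
  if (folds > n) stop("more folds than cases")
  set.seed(seed)
  fold <- rep(seq_len(folds), length.out = n)
  fold[sample.int(n)]
}

#' Instance-wise optimization of the appearance objective
#'
#' Optimizes free fields (velocity, non-correspondence logits, appearance
#' offsets) for a single 2-D image pair by Adam on the analytic gradients of
#' the appearance-adaptation objective. Used to model lesions without a
#' trained network and as an optimization sanity check.
#'
#' @param F_img,B_img 2-D fixed / moving images.
#' @param S binary lesion mask supervising the Dice term.
#' @param weights [loss_weights()]; `window` NCC window; `steps` squaring
#'   steps; `iters` Adam iterations; `lr` learning rate.
#' @return List with `v`, `N`, `A`, `phi`, `adapted`, `history` (loss per
#'   iteration).
#' @export
instance_optimize <- function(F_img, B_img, S, weights = loss_weights(),
                              window = 9, steps = 5L, iters = 200L,
                              lr = 0.05) {
  Fv <- vol_values(F_img); Bv <- vol_values(B_img); Sv <- vol_values(S) * 1
  d <- dim(Fv)
  par <- list(v = array(0, dim = c(d, 2)), z = array(-2, d),
              A = array(0, d))
  state <- adam_init(par)
  history <- numeric(iters)
  for (it in seq_len(iters)) {
    N <- 1 / (1 + exp(-par$z))
    g <- eq_appearance_grad(Fv, Bv, par$v, N, par$A, Sv, weights, window,
                            steps)
    grads <- list(v = g$dv, z = g$dN * N * (1 - N), A = g$dA)
    history[it] <- eq_appearance_loss(Fv, Bv, par$v, N, par$A, Sv, weights,
                                      window, steps)
    upd <- adam_step(par, grads, state, lr)
    par <- upd$params
    state <- upd$state
  }
  N <- 1 / (1 + exp(-par$z))
  phi <- svf_exp(par$v, steps)
  adapted <- warp_image(Bv + N * par$A, phi)
  list(v = par$v, N = N, A = par$A, phi = phi, adapted = adapted,
       history = history)
}
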