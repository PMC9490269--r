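#' Lesion-level and voxel-level evaluation
#'
#' New-lesion analyses work on connected components ("lesions") of binary
#' masks. Detection is lesion-level: a ground-truth lesion counts as detected
#' if it shares at least one voxel with any predicted lesion (the common
#' convention in the MS-lesion literature; a stricter minimum-overlap rule is
#' available via `min_overlap`).
#'
#' @name evaluation
NULL

#' Label lesions (connected components)
#'
#' @param mask binary array (2-D or 3-D).
#' @param spacing voxel size in mm.
#' @param connectivity `"full"` (26-neighbourhood in 3-D, 8 in 2-D) or
#'   `"face"`.
#' @return List of class `lesion_labeling`: `labels` (integer array, 0 =
#'   background, components numbered 1..count), `count`, `volumes_mm3`.
#' @export
label_lesions <- function(mask, spacing = rep(1, length(dim(mask))),
                          connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  mask <- vol_values(mask) > 0
  lab <- cpp_label(mask, as.integer(dim(mask)), connectivity == "full")
  count <- max(lab)
  vox_vol <- prod(spacing)
  volumes <- if (count > 0) tabulate(lab[lab > 0], count) * vox_vol else numeric(0)
  structure(list(labels = lab, count = count, volumes_mm3 = volumes,
                 spacing = spacing),
            class = "lesion_labeling")
}

#' Match predicted and ground-truth lesions
#'
#' @param pred,gt `lesion_labeling`s on the same grid.
#' @param min_overlap minimum shared voxel count for a match (default 1).
#' @return List with `detected_gt` (labels), `tp_pred`, `fp_pred`,
#'   `pairs` (data frame pred label / gt label / overlap voxels).
#' @export
match_lesions <- function(pred, gt, min_overlap = 1L) {
  if (!identical(dim(pred$labels), dim(gt$labels))) {
    stop("prediction and ground truth are on different grids")
  }
  both <- pred$labels > 0 & gt$labels > 0
  if (any(both)) {
    tab <- table(pred = pred$labels[both], gt = gt$labels[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq >= min_overlap, , drop = FALSE]
    pairs <- data.frame(pred = as.integer(as.character(df$pred)),
                        gt = as.integer(as.character(df$gt)),
                        overlap = df$Freq)
  } else {
    pairs <- data.frame(pred = integer(0), gt = integer(0),
                        overlap = integer(0))
  }
  list(detected_gt = sort(unique(pairs$gt)),
       tp_pred = sort(unique(pairs$pred)),
       fp_pred = setdiff(seq_len(pred$count), unique(pairs$pred)),
       pairs = pairs)
}

#' Lesion-level F1 score
#'
#' Harmonic mean of lesion sensitivity and lesion positive predictive value;
#' zero by convention when both are zero.
#'
#' @param sens_l,ppv_l lesion sensitivity and positive predictive value.
#' @export
f1_score <- function(sens_l, ppv_l) {
  if (sens_l + ppv_l == 0) return(0)
  2 * sens_l * ppv_l / (sens_l + ppv_l)
}

#' Lesion-level detection metrics for one patient
#'
#' For patients with ground-truth lesions: sensitivity (fraction of
#' ground-truth lesions detected), positive predictive value (fraction of
#' predicted lesions that are true positives), their F1, and whether the
#' patient is correctly flagged as progressing (`det_p`: at least one
#' ground-truth lesion detected). For lesion-free patients: the count and
#' total volume of erroneously predicted lesions, and whether the patient is
#' correctly flagged as stable (`det_s`: no lesion predicted).
#'
#' @param pred,gt binary masks or `lesion_labeling`s.
#' @param spacing voxel size in mm (ignored if labelings given).
#' @param min_overlap matching rule, see [match_lesions()].
#' @return List of class `detection_report`.
#' @export
detection_metrics <- function(pred, gt, spacing = NULL, min_overlap = 1L) {
  as_lab <- function(x) {
    if (inherits(x, "lesion_labeling")) return(x)
    sp <- if (is.null(spacing)) rep(1, length(dim(vol_values(x)))) else spacing
    label_lesions(x, sp)
  }
  pred <- as_lab(pred); gt <- as_lab(gt)
  m <- match_lesions(pred, gt, min_overlap)
  if (gt$count == 0) {
    rep_ <- list(sens_l = NA_real_, ppv_l = NA_real_, f1 = NA_real_,
                 det_p = NA, det_s = pred$count == 0,
                 fp_count = pred$count, fp_volume = sum(pred$volumes_mm3),
                 n_gt = 0L, n_pred = pred$count)
  } else {
    sens <- length(m$detected_gt) / gt$count
    ppv <- if (pred$count == 0) 0 else length(m$tp_pred) / pred$count
    rep_ <- list(sens_l = sens, ppv_l = ppv, f1 = f1_score(sens, ppv),
                 det_p = length(m$detected_gt) >= 1, det_s = NA,
                 fp_count = length(m$fp_pred),
                 fp_volume = sum(pred$volumes_mm3[m$fp_pred]),
                 n_gt = gt$count, n_pred = pred$count)
  }
  structure(rep_, class = "detection_report")
}

boundary_coords <- function(mask, spacing) {
  d <- dim(mask)
  nd <- length(d)
  inner <- array(TRUE, d)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      off <- rep(0L, nd)
      off[ax] <- s
      inner <- inner & shift_arr(mask, off, fill = FALSE)
    }
  }
  idx <- which(mask & !inner)
  if (length(idx) == 0) idx <- which(mask)
  co <- arrayInd(idx, d)
  sweep(co, 2, spacing, "*")
}

#' Voxel-overlap and surface metrics
#'
#' Dice coefficient, average symmetric surface distance (ASD) and Hausdorff
#' distance (HD) in mm between boundary voxel centres (a boundary voxel has
#' at least one face neighbour outside the mask). If exactly one of the
#' masks is empty, Dice is 0 and the distances are reported as `NA` (the
#' case is flagged); two empty masks score Dice 1 with zero distances.
#'
#' @param pred,gt binary masks on the same grid.
#' @param spacing voxel size in mm.
#' @return List of class `segmentation_report` with `dice`, `asd_mm`,
#'   `hd_mm`, `flagged_empty`.
#' @export
overlap_metrics <- function(pred, gt, spacing = rep(1, length(dim(vol_values(pred))))) {
  pred <- vol_values(pred) > 0
  gt <- vol_values(gt) > 0
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  np <- sum(pred); ng <- sum(gt)
  if (np == 0 && ng == 0) {
    return(structure(list(dice = 1, asd_mm = 0, hd_mm = 0,
                          flagged_empty = FALSE),
                     class = "segmentation_report"))
  }
  if (np == 0 || ng == 0) {
    return(structure(list(dice = 0, asd_mm = NA_real_, hd_mm = NA_real_,
                          flagged_empty = TRUE),
                     class = "segmentation_report"))
  }
  dice <- 2 * sum(pred & gt) / (np + ng)
  A <- boundary_coords(pred, spacing)
  B <- boundary_coords(gt, spacing)
  dab <- sqrt(cpp_min_sqdist(A, B))
  dba <- sqrt(cpp_min_sqdist(B, A))
  structure(list(dice = dice,
                 asd_mm = (sum(dab) + sum(dba)) / (length(dab) + length(dba)),
                 hd_mm = max(max(dab), max(dba)),
                 flagged_empty = FALSE),
            class = "segmentation_report")
}

#' Lesion-wise Dice
#'
#' Per ground-truth lesion, the Dice between that lesion and the union of
#' predicted lesions overlapping it (0 if none); averaged over all
#' ground-truth lesions (`mode = "all"`) or over detected ones only
#' (`mode = "detected"`).
#'
#' @param pred,gt `lesion_labeling`s.
#' @param mode averaging set.
#' @return Mean score, or `NA` if the selected set is empty.
#' @export
lesionwise_dice <- function(pred, gt, mode = c("all", "detected")) {
  mode <- match.arg(mode)
  if (gt$count == 0) return(NA_real_)
  m <- match_lesions(pred, gt)
  scores <- vapply(seq_len(gt$count), function(g) {
    gt_vox <- gt$labels == g
    overl <- m$pairs$pred[m$pairs$gt == g]
    if (length(overl) == 0) return(0)
    pred_vox <- pred$labels %in% overl
    2 * sum(gt_vox & pred_vox) / (sum(gt_vox) + sum(pred_vox))
  }, numeric(1))
  if (mode == "detected") {
    if (length(m$detected_gt) == 0) return(NA_real_)
    scores <- scores[m$detected_gt]
  }
  mean(scores)
}

#' Per-lesion characteristics
#'
#' Cube root of the volume (a rough diameter in mm), convexity (lesion
#' volume over the volume of its convex hull), contrast to the surrounding
#' tissue (difference of mean follow-up intensities inside the lesion and in
#' a dilated shell around it, divided by the average of the two means), and
#' contrast to the baseline (analogous, with the baseline in-lesion mean
#' replacing the shell mean).
#'
#' @param lesion_mask binary mask of a single lesion.
#' @param B,F_img baseline / follow-up images.
#' @param spacing voxel size in mm.
#' @param dilation_radius shell radius (voxels, default 2).
#' @export
lesion_characteristics <- function(lesion_mask, B, F_img,
                                   spacing = rep(1, length(dim(lesion_mask))),
                                   dilation_radius = 2) {
  lesion_mask <- vol_values(lesion_mask) > 0
  if (!any(lesion_mask)) stop("lesion mask is empty")
  Bv <- vol_values(B); Fv <- vol_values(F_img)
  vol <- sum(lesion_mask) * prod(spacing)
  hull <- mask_hull_volume(lesion_mask, spacing)
  convexity <- if (hull > 0) min(vol / hull, 1) else NA_real_
  shell <- dilate_mask(lesion_mask, dilation_radius) & !lesion_mask
  mF_les <- mean(Fv[lesion_mask])
  mF_shell <- if (any(shell)) mean(Fv[shell]) else NA_real_
  mB_les <- mean(Bv[lesion_mask])
  contrast <- function(m1, m2) {
    if (is.na(m2)) return(NA_real_)
    avg <- (m1 + m2) / 2
    if (avg == 0) return(NA_real_)
    (m1 - m2) / avg
  }
  list(volume_mm3 = vol,
       diameter_proxy = vol^(1 / 3),
       convexity = convexity,
       contrast_surround = contrast(mF_les, mF_shell),
       contrast_baseline = contrast(mF_les, mB_les))
}

#' Percentile-trimmed linear regression
#'
#' Ordinary least squares of `y` on `x` after discarding points whose `x`
#' lies outside the [lo, hi] percentile range of `x`; reports the slope and
#' the coefficient of determination.
#'
#' @param x characteristic values; `y` response (e.g. per-lesion Dice).
#' @param lo,hi trimming percentiles (defaults 0.05 / 0.95).
#' @return List with `slope`, `r_squared`, `n_used`, `flagged` (TRUE when
#'   degenerate: fewer than 3 points after trimming or zero variance in x).
#' @export
trimmed_regression <- function(x, y, lo = 0.05, hi = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  qs <- quantile(x, c(lo, hi), names = FALSE, type = 7)
  sel <- x >= qs[1] & x <= qs[2]
  x <- x[sel]; y <- y[sel]
  if (length(x) < 3 || var(x) == 0) {
    return(list(slope = NA_real_, r_squared = NA_real_, n_used = length(x),
                flagged = TRUE))
  }
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), r_squared = r2, n_used = length(x),
       flagged = FALSE)
}

#' Evaluate one patient
#'
#' Detection, overlap and lesion-wise metrics for one predicted / ground
#' truth mask pair.
#'
#' @param pred,gt binary masks; `spacing` mm.
#' @export
evaluate_patient <- function(pred, gt, spacing = rep(1, length(dim(vol_values(pred))))) {
  pl <- label_lesions(pred, spacing)
  gl <- label_lesions(gt, spacing)
  det <- detection_metrics(pl, gl)
  ov <- overlap_metrics(pred, gt, spacing)
  list(detection = det, overlap = ov,
       lesionwise_dice_all = lesionwise_dice(pl, gl, "all"),
       lesionwise_dice_detected = lesionwise_dice(pl, gl, "detected"))
}

#' Cohort summary
#'
#' Per-patient rows plus arithmetic means over patients (lesion metrics over
#' patients with ground-truth lesions, false-lesion statistics and `det_s`
#' over lesion-free patients), matching per-patient averaging rather than
#' voxel pooling.
#'
#' @param results list of [evaluate_patient()] results.
#' @param ids patient identifiers.
#' @return Data frame with one row per patient and one `cohort` summary row.
#' @export
summarize_cohort <- function(results, ids = seq_along(results)) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(id = as.character(ids[i]),
               f1 = r$detection$f1, sens_l = r$detection$sens_l,
               ppv_l = r$detection$ppv_l,
               det_p = as.numeric(r$detection$det_p),
               det_s = as.numeric(r$detection$det_s),
               fp_count = r$detection$fp_count,
               fp_volume = r$detection$fp_volume,
               dice = r$overlap$dice, asd_mm = r$overlap$asd_mm,
               hd_mm = r$overlap$hd_mm,
               lesionwise_dice_all = r$lesionwise_dice_all,
               lesionwise_dice_detected = r$lesionwise_dice_detected,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  mean_ <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  summary_row <- df[1, ]
  summary_row$id <- "cohort"
  for (col in setdiff(names(df), "id")) summary_row[[col]] <- mean_(df[[col]])
  rbind(df, summary_row)
}
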