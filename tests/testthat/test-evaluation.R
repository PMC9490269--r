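test_that("lesion labeling uses 26-connectivity and matches a flood-fill oracle", {
  expect_equal(label_lesions(array(FALSE, c(5, 5, 5)))$count, 0)
  # diagonally touching voxels form one component under full connectivity
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_equal(label_lesions(m)$count, 1)
  expect_equal(label_lesions(m, connectivity = "face")$count, 2)
  set.seed(8)
  for (rep in 1:5) {
    mask <- array(runif(10 * 9 * 8) < 0.25, c(10, 9, 8))
    lab <- label_lesions(mask)
    olab <- oracle_label(mask, full = TRUE)
    expect_equal(lab$count, max(olab))
    # identical partition up to label permutation
    expect_true(all((lab$labels > 0) == (olab > 0)))
    key <- table(lab$labels[mask], olab[mask])
    expect_true(all(rowSums(key > 0) == 1) && all(colSums(key > 0) == 1))
  }
})

test_that("lesion volumes scale with voxel volume", {
  m <- array(FALSE, c(6, 6, 6))
  m[2:3, 2:3, 2] <- TRUE
  lab <- label_lesions(m, spacing = c(0.5, 0.5, 2))
  expect_equal(lab$volumes_mm3, 4 * 0.5 * 0.5 * 2)
})

test_that("lesion matching follows the any-overlap convention", {
  gt <- array(FALSE, c(12, 12, 3))
  gt[2:4, 2:4, 2] <- TRUE
  gt[8:10, 8:10, 2] <- TRUE
  gl <- label_lesions(gt)
  # perfect prediction
  m <- match_lesions(gl, gl)
  expect_setequal(m$detected_gt, 1:2)
  expect_length(m$fp_pred, 0)
  # disjoint prediction
  pr <- array(FALSE, c(12, 12, 3))
  pr[6, 6, 1] <- TRUE
  m2 <- match_lesions(label_lesions(pr), gl)
  expect_length(m2$detected_gt, 0)
  expect_length(m2$fp_pred, 1)
  # one predicted blob overlapping two ground-truth lesions counts once as
  # a true positive but detects both
  blob <- array(FALSE, c(12, 12, 3))
  blob[2:10, 2:10, 2] <- TRUE
  m3 <- match_lesions(label_lesions(blob), gl)
  expect_setequal(m3$detected_gt, 1:2)
  expect_equal(length(m3$tp_pred), 1)
})

test_that("detection metrics combine into the harmonic-mean F1", {
  # worked example with the printed expert test-set values
  expect_equal(round(f1_score(0.609, 0.663), 3), 0.635)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0.5), 0)
  expect_equal(f1_score(0, 0), 0)
  # f1 <= max(sens, ppv) and equality when sens == ppv
  set.seed(12)
  for (i in 1:20) {
    s <- runif(1); p <- runif(1)
    expect_lte(f1_score(s, p), max(s, p) + 1e-12)
  }
  expect_equal(f1_score(0.4, 0.4), 0.4)
})

test_that("patients split into progressing and stable branches", {
  gt <- array(FALSE, c(10, 10, 4))
  gt[3:5, 3:5, 2] <- TRUE
  pred <- gt
  r <- detection_metrics(pred, gt)
  expect_equal(r$sens_l, 1)
  expect_equal(r$ppv_l, 1)
  expect_true(r$det_p)
  # lesion-free ground truth: false-positive statistics + det_s
  empty <- array(FALSE, c(10, 10, 4))
  r2 <- detection_metrics(pred, empty, spacing = c(1, 1, 2))
  expect_true(is.na(r2$sens_l))
  expect_equal(r2$fp_count, 1)
  expect_equal(r2$fp_volume, 9 * 2)
  expect_false(r2$det_s)
  r3 <- detection_metrics(empty, empty)
  expect_true(r3$det_s)
  # missed lesions: sens 0, f1 0
  r4 <- detection_metrics(empty, gt)
  expect_equal(r4$sens_l, 0)
  expect_equal(r4$f1, 0)
})

test_that("overlap metrics match hand counts and a brute-force oracle", {
  a <- array(FALSE, c(8, 8, 8))
  a[3:4, 3, 3] <- TRUE
  r <- overlap_metrics(a, a)
  expect_equal(r$dice, 1)
  expect_equal(r$asd_mm, 0)
  expect_equal(r$hd_mm, 0)
  # two 2x1x1 bars offset by one voxel: Dice 2*1/(2+2) = 0.5
  b <- array(FALSE, c(8, 8, 8))
  b[4:5, 3, 3] <- TRUE
  expect_equal(overlap_metrics(a, b)$dice, 0.5)
  # empty-vs-nonempty is flagged
  e <- array(FALSE, c(8, 8, 8))
  r2 <- overlap_metrics(e, a)
  expect_equal(r2$dice, 0)
  expect_true(is.na(r2$hd_mm))
  expect_true(r2$flagged_empty)
  # random masks against the brute-force oracle, anisotropic spacing
  set.seed(9)
  sp <- c(1, 1.5, 2)
  for (i in 1:5) {
    p <- array(runif(8^3) < 0.2, c(8, 8, 8))
    g <- array(runif(8^3) < 0.2, c(8, 8, 8))
    if (!any(p) || !any(g)) next
    r3 <- overlap_metrics(p, g, sp)
    o <- oracle_surface(p, g, sp)
    expect_equal(r3$asd_mm, o$asd, tolerance = 1e-12)
    expect_equal(r3$hd_mm, o$hd, tolerance = 1e-12)
    expect_equal(r3$dice, 2 * sum(p & g) / (sum(p) + sum(g)))
    # symmetry
    r4 <- overlap_metrics(g, p, sp)
    expect_equal(r4$dice, r3$dice)
    expect_equal(r4$hd_mm, r3$hd_mm)
  }
})

test_that("lesion-wise Dice averages over the requested lesion set", {
  gt <- array(FALSE, c(14, 14, 3))
  gt[2:4, 2:4, 2] <- TRUE    # lesion 1: 9 voxels
  gt[8:10, 8:10, 2] <- TRUE  # lesion 2: 9 voxels
  gl <- label_lesions(gt)
  expect_equal(lesionwise_dice(gl, gl, "all"), 1)
  expect_equal(lesionwise_dice(gl, gl, "detected"), 1)
  # miss lesion 2 entirely, predict lesion 1 perfectly
  pr <- array(FALSE, c(14, 14, 3))
  pr[2:4, 2:4, 2] <- TRUE
  pl <- label_lesions(pr)
  expect_equal(lesionwise_dice(pl, gl, "all"), 0.5)
  expect_equal(lesionwise_dice(pl, gl, "detected"), 1)
  # three-lesion case against hand-computed per-lesion Dice
  gt3 <- array(FALSE, c(20, 20, 1))
  gt3[2:5, 2:5, 1] <- TRUE     # 16 voxels
  gt3[10:13, 10:13, 1] <- TRUE # 16 voxels
  gt3[2:3, 16:17, 1] <- TRUE   # 4 voxels
  pr3 <- array(FALSE, c(20, 20, 1))
  pr3[2:5, 2:3, 1] <- TRUE     # 8 of lesion 1
  pr3[10:13, 10:13, 1] <- TRUE # all of lesion 2
  d1 <- 2 * 8 / (16 + 8)
  expected_all <- mean(c(d1, 1, 0))
  expected_det <- mean(c(d1, 1))
  gl3 <- label_lesions(gt3)
  pl3 <- label_lesions(pr3)
  expect_equal(lesionwise_dice(pl3, gl3, "all"), expected_all)
  expect_equal(lesionwise_dice(pl3, gl3, "detected"), expected_det)
})

test_that("lesion characteristics follow their stated formulas", {
  m <- array(FALSE, c(12, 12, 12))
  m[4:7, 4:7, 4:7] <- TRUE # solid cube
  B <- array(1, c(12, 12, 12))
  F2 <- array(1, c(12, 12, 12))
  F2[m] <- 2
  ch <- lesion_characteristics(m, B, F2, dilation_radius = 2)
  expect_equal(ch$volume_mm3, 64)
  expect_equal(ch$diameter_proxy, 4)
  expect_equal(ch$convexity, 1, tolerance = 1e-9)
  # in-lesion mean 2, shell mean 1: contrast (2-1)/1.5
  expect_equal(ch$contrast_surround, 1 / 1.5, tolerance = 1e-12)
  # identical lesion intensity in baseline and follow-up: zero contrast
  B2 <- F2
  ch2 <- lesion_characteristics(m, B2, F2)
  expect_equal(ch2$contrast_baseline, 0)
  # convexity < 1 for an L-shaped (non-convex) lesion
  L <- array(FALSE, c(12, 12, 12))
  L[2:9, 2:3, 2:3] <- TRUE
  L[2:3, 2:9, 2:3] <- TRUE
  chL <- lesion_characteristics(L, B, F2)
  expect_lt(chL$convexity, 1)
  expect_gt(chL$convexity, 0)
})

test_that("convex hull volume is exact for boxes", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:5, 3:4, 6:8] <- TRUE
  expect_equal(noncorreg:::mask_hull_volume(m), 4 * 2 * 3, tolerance = 1e-9)
  single <- array(FALSE, c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  expect_equal(noncorreg:::mask_hull_volume(single), 1, tolerance = 1e-9)
})

test_that("trimmed regression reports OLS slope and R^2 on the trimmed set", {
  x <- seq(0, 1, length.out = 40)
  expect_equal(trimmed_regression(x, 2 * x)$slope, 2, tolerance = 1e-10)
  expect_equal(trimmed_regression(x, 2 * x)$r_squared, 1, tolerance = 1e-10)
  cst <- trimmed_regression(x, rep(3, 40))
  expect_equal(cst$slope, 0, tolerance = 1e-10)
  expect_equal(cst$r_squared, 0)
  # random points against the normal-equations oracle, after trimming
  set.seed(14)
  xr <- rnorm(20)
  yr <- 1.3 * xr + rnorm(20, sd = 0.4)
  qs <- quantile(xr, c(0.05, 0.95), names = FALSE)
  keep <- xr >= qs[1] & xr <= qs[2]
  o <- oracle_ols(xr[keep], yr[keep])
  r <- trimmed_regression(xr, yr)
  expect_equal(r$slope, o$slope, tolerance = 1e-10)
  expect_equal(r$r_squared, o$r2, tolerance = 1e-10)
  expect_equal(r$n_used, sum(keep))
  # degenerate x is flagged
  expect_true(trimmed_regression(rep(1, 10), rnorm(10))$flagged)
})

test_that("cohort summaries average per patient, never pooled voxel-wise", {
  gt1 <- array(FALSE, c(10, 10, 3)); gt1[2:3, 2:3, 2] <- TRUE
  gt2 <- array(FALSE, c(10, 10, 3)); gt2[5:8, 5:8, 2] <- TRUE
  res <- list(evaluate_patient(gt1, gt1), evaluate_patient(array(FALSE, c(10, 10, 3)), gt2))
  df <- summarize_cohort(res, ids = c("p1", "p2"))
  expect_equal(nrow(df), 3)
  cohort_row <- df[df$id == "cohort", ]
  expect_equal(cohort_row$dice, mean(c(1, 0)))
  expect_equal(cohort_row$f1, mean(c(1, 0)))
})
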