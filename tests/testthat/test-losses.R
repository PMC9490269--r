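test_that("NCC distance is zero for identical and affinely rescaled images", {
  img <- smooth_image(c(24, 24), seed = 1)
  expect_lt(ncc_distance(img, img), 1e-4)
  expect_lt(ncc_distance(img, 2.5 * img + 1), 1e-4)
  expect_lt(ncc_distance(img, img, window = "global"), 1e-6)
  # perfectly anti-correlated patches: 1 - (-1)^2 = 0
  p1 <- matrix(1:9, 3, byrow = TRUE)
  p2 <- matrix(9:1, 3, byrow = TRUE)
  expect_lt(ncc_distance(p1, p2, window = "global"), 1e-6)
  # uncorrelated noise is far from zero, and the value stays in [0, 1]
  set.seed(2)
  a <- matrix(rnorm(400), 20)
  b <- matrix(rnorm(400), 20)
  d <- ncc_distance(a, b)
  expect_gt(d, 0.3)
  expect_lte(d, 1)
  # zero-variance input never yields NaN
  expect_false(is.nan(ncc_distance(matrix(1, 8, 8), matrix(2, 8, 8))))
})

test_that("masking removes the distance contribution of flagged regions", {
  f <- smooth_image(c(20, 20), seed = 3)
  m <- smooth_image(c(20, 20), seed = 4)
  expect_equal(masked_distance(f, m, N = array(1, c(20, 20))), 0)
  expect_equal(masked_distance(f, m, N = array(0, c(20, 20))),
               ncc_distance(f, m), tolerance = 1e-14)
  # two identical images except inside a patch; masking the patch shrinks
  # the distance below the unmasked value
  m2 <- f
  m2[8:12, 8:12] <- m2[8:12, 8:12] + 3
  N <- array(0, c(20, 20))
  N[8:12, 8:12] <- 1
  expect_lt(masked_distance(f, m2, N, window = "global"),
            masked_distance(f, m2, NULL, window = "global"))
  expect_error(masked_distance(f, m2, N * 2), "\\[0, 1\\]")
})

test_that("velocity smoothness penalty counts squared gradients and is 2-homogeneous", {
  d <- c(10, 10)
  v <- identity_field(d)
  v[, , 1] <- 5
  expect_equal(smoothness_reg(v), 0)
  # a single linear ramp in one of 2 components x 2 axes -> 1/4
  ramp <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  v[, , 1] <- ramp
  expect_equal(smoothness_reg(v), 0.25)
  w <- smooth_velocity(d, max_mag = 2, seed = 6)
  expect_equal(smoothness_reg(3 * w), 9 * smoothness_reg(w),
               tolerance = 1e-12)
})

test_that("non-correspondence regularizer: area plus bounded boundary term", {
  z <- array(0, c(5, 5))
  expect_equal(noncorr_reg(z), 0)
  ones <- array(1, c(5, 5))
  expect_equal(noncorr_reg(ones, gamma = 1), 1) # gradient vanishes
  # single centre voxel: area 1/25 plus tanh of the RMS gradient magnitude;
  # hand count: four central differences of +/- 0.5 -> sum sq = 1 over 50
  single <- z
  single[3, 3] <- 1
  expected <- 1 / 25 + tanh(sqrt(1 / 50))
  expect_equal(noncorr_reg(single, gamma = 1), expected, tolerance = 1e-12)
  # monotone nondecreasing in gamma
  expect_gte(noncorr_reg(single, gamma = 2), noncorr_reg(single, gamma = 1))
  # the per-voxel tanh variant agrees with a direct computation and has a
  # matching analytic gradient
  set.seed(77)
  Np <- array(runif(64, 0.1, 0.9), c(8, 8))
  g <- spatial_gradient(Np)
  direct <- mean(Np) + 0.7 * mean(tanh(sqrt(g[, , 1]^2 + g[, , 2]^2)))
  expect_equal(noncorr_reg(Np, gamma = 0.7, per_voxel = TRUE), direct,
               tolerance = 1e-12)
  gr <- noncorreg:::noncorr_reg_grad(Np, gamma = 0.7, per_voxel = TRUE)
  i <- 23
  eps <- 1e-6
  Na <- Np; Na[i] <- Na[i] + eps
  Nb <- Np; Nb[i] <- Nb[i] - eps
  fd <- (noncorr_reg(Na, 0.7, TRUE) - noncorr_reg(Nb, 0.7, TRUE)) / (2 * eps)
  expect_equal(gr[i], fd, tolerance = 1e-5)
})

test_that("Dice loss matches its closed form", {
  t <- array(0, c(8, 8))
  t[2:5, 3:6] <- 1
  expect_lt(dice_loss(t, t), 1e-4)
  expect_lt(dice_loss(t * 0, t * 0), 1e-4) # empty/empty is perfect
  half <- t
  half[2:5, 3:4] <- 0 # half of the target voxels
  expect_equal(dice_loss(half, t), 1 / 3, tolerance = 1e-4)
})

test_that("deep supervision weights the finest level most", {
  expect_equal(deep_supervision(c(1, 1, 1)), 1.0)
  expect_equal(deep_supervision(c(1, 0, 0)), 0.7)
  expect_equal(deep_supervision(c(0, 0, 2)), 0.2)
  expect_error(deep_supervision(c(1, 1), c(0.7, 0.2, 0.1)), "differ")
  expect_error(loss_weights(level_weights = c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("the unsupervised objective is zero at the perfect configuration", {
  B <- smooth_image(c(16, 16), seed = 8)
  v0 <- identity_field(c(16, 16))
  N0 <- array(0, c(16, 16))
  expect_lt(eq_noncorr_loss(B, B, v0, N0), 1e-4)
  # with alpha = beta = 0 it reduces to the masked distance
  w0 <- loss_weights(alpha = 0, beta = 0)
  F2 <- smooth_image(c(16, 16), seed = 9)
  expect_equal(eq_noncorr_loss(F2, B, v0, N0, w0),
               masked_distance(F2, B, N0), tolerance = 1e-12)
})

test_that("raising N over a non-correspondent region trades distance for regularization", {
  B <- smooth_image(c(20, 20), seed = 10)
  F2 <- B
  F2[8:13, 8:13] <- F2[8:13, 8:13] + 4 # a "new lesion"
  v0 <- identity_field(c(20, 20))
  region <- array(0, c(20, 20))
  region[8:13, 8:13] <- 1
  w <- loss_weights(alpha = 0, beta = 0)
  dist_at <- function(s) masked_distance(F2, B, region * s)
  expect_gt(dist_at(0), dist_at(0.5))
  expect_gt(dist_at(0.5), dist_at(1))
  reg_at <- function(s) noncorr_reg(region * s)
  expect_gt(reg_at(1), reg_at(0.5))
  expect_gt(reg_at(0.5), reg_at(0))
})

test_that("the appearance objective vanishes trivially and drops under optimization", {
  B <- smooth_image(c(16, 16), seed = 11)
  v0 <- identity_field(c(16, 16))
  z0 <- array(0, c(16, 16))
  expect_lt(eq_appearance_loss(B, B, v0, z0, z0, z0), 1e-4)
  # N == 0 reduces to registration distance + alpha R + beta Dice(0, S)
  F2 <- smooth_image(c(16, 16), seed = 12)
  S <- z0; S[4:6, 4:6] <- 1
  w <- loss_weights()
  expect_equal(eq_appearance_loss(F2, B, v0, z0, z0, S, w),
               ncc_distance(F2, B) + w$beta * dice_loss(z0, S),
               tolerance = 1e-12)
  # instance-wise optimization beats the trivial configuration
  Bl <- smooth_image(c(24, 24), sigma = 3, seed = 13)
  Fl <- Bl
  Fl[10:15, 10:15] <- Fl[10:15, 10:15] + 2
  Sl <- array(0, c(24, 24)); Sl[10:15, 10:15] <- 1
  base <- eq_appearance_loss(Fl, Bl, identity_field(c(24, 24)),
                             array(0, c(24, 24)), array(0, c(24, 24)), Sl,
                             steps = 4)
  opt <- instance_optimize(Fl, Bl, Sl, iters = 120, steps = 4)
  expect_lt(tail(opt$history, 1), base)
})

test_that("analytic gradients of every objective match finite differences", {
  set.seed(21)
  d <- c(10, 10)
  B <- smooth_image(d, seed = 21)
  F2 <- smooth_image(d, seed = 22)
  v <- smooth_velocity(d, max_mag = 0.8, sigma = 2, seed = 23)
  N <- array(runif(prod(d), 0.05, 0.9), d)
  A <- smooth_image(d, seed = 24)
  S <- array(0, d); S[3:5, 4:7] <- 1
  w <- loss_weights()
  fd_max_rel <- function(loss_fn, x, gx, n = 15, eps = 1e-6) {
    idx <- sample(length(x), n)
    rel <- vapply(idx, function(i) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (loss_fn(xp) - loss_fn(xm)) / (2 * eps)
      abs(fd - gx[i]) / max(abs(fd), abs(gx[i]), 1e-8)
    }, numeric(1))
    max(rel)
  }
  g1 <- noncorreg:::eq_noncorr_grad(F2, B, v, N, w, window = 5, steps = 4)
  expect_lt(fd_max_rel(function(x) eq_noncorr_loss(F2, B, x, N, w, 5, 4),
                       v, g1$dv), 1e-3)
  expect_lt(fd_max_rel(function(x) eq_noncorr_loss(F2, B, v, x, w, 5, 4),
                       N, g1$dN), 1e-3)
  g2 <- noncorreg:::eq_appearance_grad(F2, B, v, N, A, S, w, 5, 4)
  expect_lt(fd_max_rel(function(x) eq_appearance_loss(F2, B, x, N, A, S, w, 5, 4),
                       v, g2$dv), 1e-3)
  expect_lt(fd_max_rel(function(x) eq_appearance_loss(F2, B, v, x, A, S, w, 5, 4),
                       N, g2$dN), 1e-3)
  expect_lt(fd_max_rel(function(x) eq_appearance_loss(F2, B, v, N, x, S, w, 5, 4),
                       A, g2$dA), 1e-3)
  g3 <- noncorreg:::pretrain_grad(v, svf_exp(v * 0.5, 4), N, S, steps = 4)
  expect_lt(fd_max_rel(function(x) pretrain_loss(x, svf_exp(v * 0.5, 4), N, S, 4),
                       v, g3$dv), 1e-3)
  expect_lt(fd_max_rel(function(x) pretrain_loss(v, svf_exp(v * 0.5, 4), x, S, 4),
                       N, g3$dN), 1e-3)
})

test_that("pre-training loss combines Dice and deformation error", {
  d <- c(12, 12)
  S <- array(0, d); S[4:6, 4:6] <- 1
  gt_phi <- identity_field(d)
  # perfect prediction
  expect_lt(pretrain_loss(identity_field(d), gt_phi, S, S), 1e-4)
  # zero prediction against a translation by c: deformation term c^2
  gt_phi[, , 2] <- 1.5
  val <- pretrain_loss(identity_field(d), gt_phi, S, S)
  expect_equal(val, 1.5^2, tolerance = 1e-4)
  # random case against an independently coded sum of the two terms
  set.seed(31)
  v <- smooth_velocity(d, max_mag = 1, sigma = 2, seed = 31)
  N <- array(runif(prod(d)), d)
  oracle <- dice_loss(N, S) + sum((svf_exp(v, 7) - gt_phi)^2) / prod(d)
  expect_equal(pretrain_loss(v, gt_phi, N, S), oracle, tolerance = 1e-12)
})
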