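test_that("the exponential of the zero field is the identity", {
  v <- identity_field(c(12, 10))
  phi <- svf_exp(v)
  expect_equal(max(abs(phi)), 0)
  img <- smooth_image(c(12, 10), seed = 1)
  expect_equal(warp_image(img, phi), img)
  # 3-D as well
  v3 <- identity_field(c(8, 8, 6))
  expect_equal(max(abs(svf_exp(v3))), 0)
})

test_that("a constant velocity exponentiates to the same translation", {
  v <- identity_field(c(20, 20))
  v[, , 2] <- 1.5
  phi <- svf_exp(v, steps = 7)
  interior <- phi[5:15, 5:15, ]
  expect_equal(max(abs(interior[, , 1])), 0, tolerance = 1e-10)
  expect_equal(interior[, , 2], array(1.5, dim = c(11, 11)),
               tolerance = 1e-10)
})

test_that("warping with an integer translation shifts with replicated border", {
  img <- matrix(seq_len(20), 4, 5)
  phi <- identity_field(c(4, 5))
  phi[, , 2] <- 1 # sample at j + 1
  out <- warp_image(img, phi)
  expect_equal(out[, 1:4], img[, 2:5])
  expect_equal(out[, 5], img[, 5])
})

test_that("smooth small-magnitude velocities give diffeomorphic deformations", {
  v <- smooth_velocity(c(32, 32), max_mag = 2, seed = 42)
  phi <- svf_exp(v, steps = 7)
  jd <- jacobian_determinant(phi)
  expect_gt(min(jd[3:30, 3:30]), 0)
  # inverse consistency: warp with exp(v) then exp(-v) restores the image
  img <- smooth_image(c(32, 32), seed = 2)
  round_trip <- warp_image(warp_image(img, phi), svf_exp(-v, steps = 7))
  mae <- mean(abs(round_trip - img)) / diff(range(img))
  expect_lt(mae, 0.02)
})

test_that("doubling the squaring steps has converged for |v| <= 2", {
  v <- smooth_velocity(c(24, 24), max_mag = 2, seed = 5)
  d1 <- svf_exp(v, steps = 7)
  d2 <- svf_exp(v, steps = 14)
  expect_lt(max(abs(d1 - d2)), 0.1)
})

test_that("composition has identity elements and adds translations", {
  u <- smooth_velocity(c(16, 16), max_mag = 1.5, seed = 9)
  id <- identity_field(c(16, 16))
  expect_equal(compose_fields(id, u), u, tolerance = 1e-12)
  expect_equal(compose_fields(u, id), u, tolerance = 1e-12)
  a <- id; a[, , 1] <- 0.7; a[, , 2] <- -0.2
  b <- id; b[, , 1] <- -0.3; b[, , 2] <- 0.4
  ab <- compose_fields(a, b)
  expect_equal(ab[5:12, 5:12, 1], array(0.4, c(8, 8)), tolerance = 1e-9)
  expect_equal(ab[5:12, 5:12, 2], array(0.2, c(8, 8)), tolerance = 1e-9)
  # associativity on constant fields, up to interpolation error
  cfd <- id; cfd[, , 1] <- 0.25
  lhs <- compose_fields(compose_fields(a, b), cfd)
  rhs <- compose_fields(a, compose_fields(b, cfd))
  expect_lt(max(abs(lhs[4:12, 4:12, ] - rhs[4:12, 4:12, ])), 1e-6)
})

test_that("spatial gradients use central differences with one-sided borders", {
  # constant field
  expect_equal(max(abs(spatial_gradient(matrix(3, 6, 6)))), 0)
  # linear ramp along axis 1
  ramp <- matrix(rep(seq_len(8), 5), 8, 5)
  g <- spatial_gradient(ramp)
  expect_equal(g[, , 1], matrix(1, 8, 5))
  expect_equal(max(abs(g[, , 2])), 0)
  # f(x) = x^2 on integers: central difference at x = 3 is 6
  f <- matrix((0:6)^2, 7, 3)
  g <- spatial_gradient(f)
  expect_equal(g[4, 2, 1], 6) # row 4 holds x = 3
})

test_that("difference operator and its adjoint satisfy the dot-product identity", {
  set.seed(3)
  x <- matrix(rnorm(30), 5, 6)
  y <- matrix(rnorm(30), 5, 6)
  for (ax in 1:2) {
    lhs <- sum(noncorreg:::diff_axis(x, ax) * y)
    rhs <- sum(x * noncorreg:::diff_axis_adjoint(y, ax))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("geometry errors are informative", {
  v <- identity_field(c(8, 8))
  v[1, 1, 1] <- NaN
  expect_error(svf_exp(v), "non-finite")
  img <- matrix(0, 4, 4)
  expect_error(warp_image(img, identity_field(c(5, 5))), "4,4")
  expect_error(spatial_gradient(matrix(1, 1, 5)), "axis")
  expect_error(compose_fields(identity_field(c(4, 4)),
                              identity_field(c(5, 5))), "differ")
})
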