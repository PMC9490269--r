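test_that("configuration invariants are enforced", {
  expect_error(network_config(in_slices = 4), "odd")
  expect_error(network_config(depth = 2, out_levels = 3), "out_levels")
  cfg <- network_config()
  expect_equal(cfg$in_slices, 5L)
  expect_equal(cfg$slab_height, 368L)
  expect_equal(cfg$slab_width, 512L)
})

test_that("outputs appear on three dyadically downsampled levels", {
  # full nominal slab size, minimal channel width to keep this quick
  cfg <- network_config(in_slices = 5, base_channels = 2, depth = 3,
                        out_levels = 3)
  model <- build_network(cfg, seed = 1)
  set.seed(2)
  B <- array(rnorm(368 * 512 * 5), dim = c(368, 512, 5))
  F2 <- array(rnorm(368 * 512 * 5), dim = c(368, 512, 5))
  out <- net_forward(model, B, F2)
  expect_length(out$levels, 3)
  expect_equal(dim(out$levels[[1]]$N), c(368, 512))
  expect_equal(dim(out$levels[[2]]$N), c(184, 256))
  expect_equal(dim(out$levels[[3]]$N), c(92, 128))
  expect_equal(dim(out$levels[[1]]$v), c(368, 512, 2))
  expect_equal(dim(out$levels[[1]]$A), c(368, 512))
})

test_that("indivisible slab sizes fail with the required padding", {
  model <- tiny_net(slab = 32)
  B <- array(0, dim = c(30, 32, 3))
  expect_error(net_forward(model, B, B), "pad to 32x32")
})

test_that("zeroed final layers give the identity deformation", {
  model <- tiny_net(seed = 5)
  for (lv in seq_along(model$params$head_v)) {
    model$params$head_v[[lv]]$W[] <- 0
    model$params$head_v[[lv]]$b[] <- 0
  }
  set.seed(3)
  B <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3))
  out <- net_forward(model, B, B + 0.1)
  expect_equal(max(abs(out$levels[[1]]$v)), 0)
  expect_equal(max(abs(svf_exp(out$levels[[1]]$v))), 0)
})

test_that("the segmentation head is bounded in [0,1] across random inputs and weights", {
  for (s in 1:10) {
    model <- tiny_net(seed = s, slab = 16, base = 2, depth = 2, out_levels = 2)
    set.seed(100 + s)
    B <- array(rnorm(16 * 16 * 3, sd = 3), dim = c(16, 16, 3))
    F2 <- array(rnorm(16 * 16 * 3, sd = 3), dim = c(16, 16, 3))
    out <- net_forward(model, B, F2)
    for (lv in 1:2) {
      expect_gte(min(out$levels[[lv]]$N), 0)
      expect_lte(max(out$levels[[lv]]$N), 1)
    }
  }
})

test_that("forward passes are deterministic for fixed seed, config and input", {
  m1 <- tiny_net(seed = 11)
  m2 <- tiny_net(seed = 11)
  expect_identical(m1$params, m2$params)
  set.seed(4)
  B <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3))
  o1 <- net_forward(m1, B, B * 1.1)
  o2 <- net_forward(m2, B, B * 1.1)
  expect_identical(o1$levels, o2$levels)
})

test_that("parameter counting is deterministic and scales with width", {
  m1 <- tiny_net(seed = 1)
  m2 <- tiny_net(seed = 2)
  expect_identical(count_parameters(m1), count_parameters(m2))
  m_wide <- tiny_net(seed = 1, base = 4)
  expect_gt(count_parameters(m_wide), count_parameters(m1))
  # hand count for one conv: cout * cin * k^2 weights + cout biases
  cp <- noncorreg:::init_conv(3, 4, 3)
  expect_equal(length(cp$W) + length(cp$b), 4 * 3 * 9 + 4)
})

test_that("backpropagation matches finite differences through the whole net", {
  model <- tiny_net(seed = 3, slab = 16, base = 2, depth = 2, out_levels = 2)
  set.seed(99)
  B <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  F2 <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  loss_of <- function(m) {
    f <- net_forward(m, B, F2)
    s <- 0
    for (lv in 1:2) {
      o <- f$levels[[lv]]
      s <- s + sum(o$v^2) + sum(o$N^2) + sum(o$A^2)
    }
    s
  }
  fwd <- net_forward(model, B, F2, train = TRUE)
  lg <- lapply(1:2, function(lv) {
    o <- fwd$levels[[lv]]
    list(dv = 2 * o$v, dN = 2 * o$N, dA = 2 * o$A)
  })
  G <- noncorreg:::net_backward(model, fwd, lg)
  paths <- list(list("blk_img", "c1", "W"), list("blk_sub", "c2", "W"),
                list("enc", 1L, "c1", "W"), list("enc", 3L, "c2", "W"),
                list("dec_flow", 1L, "c1", "W"), list("dec_seg", 2L, "c2", "W"),
                list("head_v", 1L, "W"), list("head_N", 2L, "W"),
                list("head_A", 1L, "W"))
  assign_rec <- function(tree, path, val) {
    if (length(path) == 1) {
      tree[[path[[1]]]] <- val
      return(tree)
    }
    tree[[path[[1]]]] <- assign_rec(tree[[path[[1]]]], path[-1], val)
    tree
  }
  rels <- c()
  for (p in paths) {
    arr <- Reduce(function(a, b) a[[b]], p, model$params)
    garr <- Reduce(function(a, b) a[[b]], p, G)
    # median over several entries: finite differences can cross maxpool /
    # leaky-ReLU kinks at isolated entries
    ix <- sample(length(arr), min(5, length(arr)))
    rel <- vapply(ix, function(i) {
      eps <- 1e-5
      ap <- arr; ap[i] <- ap[i] + eps
      am <- arr; am[i] <- am[i] - eps
      mp <- model; mp$params <- assign_rec(model$params, p, ap)
      mm <- model; mm$params <- assign_rec(model$params, p, am)
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      abs(fd - garr[i]) / max(abs(fd), abs(garr[i]), 1e-8)
    }, numeric(1))
    rels <- c(rels, median(rel))
  }
  expect_lt(max(rels), 1e-4)
})

test_that("checkpoints round-trip with config and version stamp", {
  model <- tiny_net(seed = 8)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$cfg, model$cfg)
  expect_error(load_checkpoint({
    p2 <- tempfile(fileext = ".rds")
    saveRDS(list(a = 1), p2)
    p2
  }), "checkpoint")
})
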