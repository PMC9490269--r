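#' Two-decoder registration / segmentation network
#'
#' A compact U-Net-style architecture for 2.5-D slab input: baseline and
#' follow-up slabs enter one initial convolutional block, their subtraction
#' image a second one; the concatenated features pass through a max-pooling
#' encoder, and two decoders with skip connections emit (1) an in-plane
#' stationary velocity field and (2) a non-correspondence map `N` (sigmoid,
#' bounded in `[0, 1]`) together with appearance offsets `A` (linear).
#' Outputs are produced on the finest `out_levels` resolutions for deep
#' supervision. All forward and backward passes are written against compiled
#' conv kernels, so gradients are exact.
#'
#' @name network
NULL

#' Network configuration
#'
#' @param in_slices odd number of stacked axial slices (default 5; the
#'   central slice is the one whose prediction is kept at inference).
#' @param base_channels feature maps at the finest level.
#' @param depth number of pooling levels.
#' @param out_levels number of deeply supervised output resolutions.
#' @param slab_height,slab_width nominal in-plane input size (default
#'   368 x 512); any size divisible by `2^depth` is accepted at run time.
#' @param vel_scale factor applied to the raw velocity head output (voxels).
#' @export
network_config <- function(in_slices = 5L, base_channels = 8L, depth = 3L,
                           out_levels = 3L, slab_height = 368L,
                           slab_width = 512L, vel_scale = 1) {
  if (in_slices %% 2 != 1) stop("`in_slices` must be odd")
  if (out_levels > depth) stop("`out_levels` must not exceed `depth`")
  stopifnot(base_channels >= 1, depth >= 1, out_levels >= 1)
  structure(list(in_slices = as.integer(in_slices),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 out_levels = as.integer(out_levels),
                 slab_height = as.integer(slab_height),
                 slab_width = as.integer(slab_width),
                 vel_scale = vel_scale),
            class = "network_config")
}

lrelu <- function(z) ifelse(z > 0, z, 0.1 * z)
lrelu_grad <- function(z) ifelse(z > 0, 1, 0.1)

init_conv <- function(cin, cout, k, sd_scale = 1) {
  sd <- sd_scale * sqrt(2 / (cin * k * k))
  list(W = matrix(rnorm(cout * cin * k * k, sd = sd), nrow = cout),
       b = rep(0, cout), k = as.integer(k))
}

init_block <- function(cin, cout, k = 3L) {
  list(c1 = init_conv(cin, cout, k), c2 = init_conv(cout, cout, k))
}

net_channels <- function(cfg) {
  cfg$base_channels * 2^(seq_len(cfg$depth + 1L) - 1L)
}

#' Build a network
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the weight initialization (determinism:
#'   identical seed and config give identical parameters).
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  S <- cfg$in_slices
  C <- cfg$base_channels
  ch <- net_channels(cfg)
  p <- list()
  p$blk_img <- init_block(2L * S, C)
  p$blk_sub <- init_block(S, C)
  p$enc <- vector("list", cfg$depth + 1L)
  p$enc[[1]] <- init_block(2L * C, ch[1])
  for (l in 2:(cfg$depth + 1L)) p$enc[[l]] <- init_block(ch[l - 1], ch[l])
  for (dec in c("dec_flow", "dec_seg")) {
    blocks <- vector("list", cfg$depth)
    for (l in seq_len(cfg$depth)) {
      blocks[[l]] <- init_block(ch[l + 1] + ch[l], ch[l])
    }
    p[[dec]] <- blocks
  }
  p$head_v <- p$head_N <- p$head_A <- vector("list", cfg$out_levels)
  for (lv in seq_len(cfg$out_levels)) {
    p$head_v[[lv]] <- init_conv(ch[lv], 2L, 1L, sd_scale = 1e-2)
    p$head_N[[lv]] <- init_conv(ch[lv], 1L, 1L)
    # start from a low lesion prior: new lesions are rare
    p$head_N[[lv]]$b <- -2
    p$head_A[[lv]] <- init_conv(ch[lv], 1L, 1L, sd_scale = 1e-1)
  }
  structure(list(cfg = cfg, params = p, version = "0.1.0"),
            class = "noncorr_net")
}

#' Count trainable parameters
#' @param model a built network.
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) {
      n <<- n + length(x)
    } else if (is.list(x)) {
      for (e in x) walk(e)
    }
  }
  walk(model$params)
  n
}

conv_fwd <- function(cp, x) {
  cpp_conv2d_fwd(x, cp$W, cp$b, cp$k)
}

block_fwd <- function(bp, x) {
  z1 <- conv_fwd(bp$c1, x)
  a1 <- lrelu(z1)
  z2 <- conv_fwd(bp$c2, a1)
  list(y = lrelu(z2), cache = list(x = x, z1 = z1, a1 = a1, z2 = z2))
}

block_bwd <- function(bp, cache, dy) {
  dz2 <- dy * lrelu_grad(cache$z2)
  b2 <- cpp_conv2d_bwd(cache$a1, bp$c2$W, dz2, bp$c2$k)
  dz1 <- b2$dx * lrelu_grad(cache$z1)
  b1 <- cpp_conv2d_bwd(cache$x, bp$c1$W, dz1, bp$c1$k)
  list(dx = b1$dx,
       grads = list(c1 = list(W = b1$dW, b = as.numeric(b1$db)),
                    c2 = list(W = b2$dW, b = as.numeric(b2$db))))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

as_chw <- function(x) {
  if (length(dim(x)) == 2L) array(x, dim = c(dim(x), 1L)) else x
}

#' Forward pass
#'
#' @param model a built network.
#' @param B_slab,F_slab arrays `(H, W, in_slices)`; `H` and `W` must be
#'   divisible by `2^depth`.
#' @param train keep intermediate activations for a backward pass.
#' @return A list with element `levels`: per output level (finest first) a
#'   list with `v` (H, W, 2 velocity field), `N` (sigmoid map in `[0, 1]`)
#'   and `A` (appearance offsets), the grid downsampled by `2^(level-1)`.
#' @export
net_forward <- function(model, B_slab, F_slab, train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(B_slab)
  if (!identical(dim(F_slab), d)) stop("slab shapes differ")
  if (d[3] != cfg$in_slices) stop("slab must have `in_slices` slices")
  div <- 2^cfg$depth
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf(
      "slab size %dx%d not divisible by 2^depth = %d; pad to %dx%d",
      d[1], d[2], div, ceiling(d[1] / div) * div, ceiling(d[2] / div) * div))
  }
  x_img <- array(c(B_slab, F_slab), dim = c(d[1], d[2], 2L * d[3]))
  x_sub <- F_slab - B_slab
  fi <- block_fwd(p$blk_img, x_img)
  fs <- block_fwd(p$blk_sub, x_sub)
  x0 <- cat_channels(fi$y, fs$y)

  e <- vector("list", cfg$depth + 1L)
  caches <- list(fi = fi$cache, fs = fs$cache, enc = vector("list", cfg$depth + 1L),
                 pool = vector("list", cfg$depth))
  b <- block_fwd(p$enc[[1]], x0)
  e[[1]] <- b$y; caches$enc[[1]] <- b$cache
  for (l in seq_len(cfg$depth)) {
    pl <- cpp_maxpool2_fwd(e[[l]])
    caches$pool[[l]] <- list(idx = pl$idx, H = dim(e[[l]])[1], W = dim(e[[l]])[2])
    b <- block_fwd(p$enc[[l + 1L]], pl$y)
    e[[l + 1L]] <- b$y; caches$enc[[l + 1L]] <- b$cache
  }

  decode <- function(blocks) {
    dcaches <- vector("list", cfg$depth)
    dfeat <- vector("list", cfg$depth)
    u <- e[[cfg$depth + 1L]]
    for (l in rev(seq_len(cfg$depth))) {
      up <- cpp_upsample2_fwd(u)
      ct <- cat_channels(up, e[[l]])
      b <- block_fwd(blocks[[l]], ct)
      u <- b$y
      dfeat[[l]] <- u
      dcaches[[l]] <- b$cache
    }
    list(feat = dfeat, caches = dcaches)
  }
  df <- decode(p$dec_flow)
  ds <- decode(p$dec_seg)

  levels <- vector("list", cfg$out_levels)
  head_caches <- vector("list", cfg$out_levels)
  for (lv in seq_len(cfg$out_levels)) {
    vr <- conv_fwd(p$head_v[[lv]], df$feat[[lv]])
    zN <- conv_fwd(p$head_N[[lv]], ds$feat[[lv]])[, , 1]
    Ao <- conv_fwd(p$head_A[[lv]], ds$feat[[lv]])[, , 1]
    Nmap <- 1 / (1 + exp(-zN))
    v <- array(vr, dim = dim(vr)) * cfg$vel_scale
    levels[[lv]] <- list(v = v, N = Nmap, A = Ao)
    head_caches[[lv]] <- list(N = Nmap)
  }
  out <- list(levels = levels)
  if (train) {
    out$cache <- list(caches = caches, dec_flow = df, dec_seg = ds,
                      heads = head_caches, e = e, x0dims = dim(x0),
                      fi_y_ch = dim(fi$y)[3])
  }
  out
}

zero_grads_like <- function(p) {
  rapply(p, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

#' Backward pass
#'
#' Propagates gradients on the per-level head outputs (`dv` w.r.t. the
#' velocity field, `dN` w.r.t. the sigmoid output, `dA` w.r.t. the offsets)
#' back to all parameters.
#'
#' @param model network; `fwd` the result of `net_forward(..., train = TRUE)`;
#'   `level_grads` list per level with `dv`, `dN`, `dA` (any may be NULL).
#' @return List of parameter gradients with the same structure as
#'   `model$params`.
#' @keywords internal
net_backward <- function(model, fwd, level_grads) {
  cfg <- model$cfg
  p <- model$params
  ca <- fwd$cache
  G <- list()
  dflow_feat <- vector("list", cfg$depth)
  dseg_feat <- vector("list", cfg$depth)
  G$head_v <- G$head_N <- G$head_A <- vector("list", cfg$out_levels)

  for (lv in seq_len(cfg$out_levels)) {
    lg <- level_grads[[lv]]
    featF <- ca$dec_flow$feat[[lv]]
    featS <- ca$dec_seg$feat[[lv]]
    hd <- dim(featF)
    dF_acc <- array(0, dim = hd)
    dS_acc <- array(0, dim = dim(featS))
    if (!is.null(lg$dv)) {
      dvr <- lg$dv * cfg$vel_scale
      bb <- cpp_conv2d_bwd(featF, p$head_v[[lv]]$W, dvr, 1L)
      dF_acc <- dF_acc + bb$dx
      G$head_v[[lv]] <- list(W = bb$dW, b = as.numeric(bb$db))
    } else {
      G$head_v[[lv]] <- list(W = p$head_v[[lv]]$W * 0,
                             b = p$head_v[[lv]]$b * 0)
    }
    if (!is.null(lg$dN) || !is.null(lg$dzN)) {
      Nmap <- fwd$levels[[lv]]$N
      dzN <- 0
      if (!is.null(lg$dN)) dzN <- dzN + lg$dN * Nmap * (1 - Nmap)
      if (!is.null(lg$dzN)) dzN <- dzN + lg$dzN
      bb <- cpp_conv2d_bwd(featS, p$head_N[[lv]]$W, as_chw(dzN), 1L)
      dS_acc <- dS_acc + bb$dx
      G$head_N[[lv]] <- list(W = bb$dW, b = as.numeric(bb$db))
    } else {
      G$head_N[[lv]] <- list(W = p$head_N[[lv]]$W * 0,
                             b = p$head_N[[lv]]$b * 0)
    }
    if (!is.null(lg$dA)) {
      bb <- cpp_conv2d_bwd(featS, p$head_A[[lv]]$W, as_chw(lg$dA), 1L)
      dS_acc <- dS_acc + bb$dx
      G$head_A[[lv]] <- list(W = bb$dW, b = as.numeric(bb$db))
    } else {
      G$head_A[[lv]] <- list(W = p$head_A[[lv]]$W * 0,
                             b = p$head_A[[lv]]$b * 0)
    }
    dflow_feat[[lv]] <- dF_acc
    dseg_feat[[lv]] <- dS_acc
  }

  de <- vector("list", cfg$depth + 1L)
  for (l in seq_len(cfg$depth + 1L)) de[[l]] <- ca$e[[l]] * 0

  backprop_decoder <- function(blocks, dcaches, dfeat, name) {
    gb <- vector("list", cfg$depth)
    dup_next <- NULL
    for (l in seq_len(cfg$depth)) {
      dy <- if (!is.null(dfeat[[l]])) dfeat[[l]] else
        array(0, dim = dim(ca[[name]]$feat[[l]]))
      if (!is.null(dup_next)) dy <- dy + dup_next
      bb <- block_bwd(blocks[[l]], dcaches[[l]], dy)
      gb[[l]] <- bb$grads
      nup <- dim(ca$e[[l + 1L]])[3]
      dct <- bb$dx
      dup <- dct[, , seq_len(nup), drop = FALSE]
      de[[l]] <<- de[[l]] + dct[, , nup + seq_len(dim(ca$e[[l]])[3]), drop = FALSE]
      dup_next_ <- cpp_upsample2_bwd(dup)
      if (l == cfg$depth) {
        de[[cfg$depth + 1L]] <<- de[[cfg$depth + 1L]] + dup_next_
        dup_next <- NULL
      } else {
        dup_next <- dup_next_
      }
    }
    gb
  }
  G$dec_flow <- backprop_decoder(p$dec_flow, ca$dec_flow$caches, dflow_feat,
                                 "dec_flow")
  G$dec_seg <- backprop_decoder(p$dec_seg, ca$dec_seg$caches, dseg_feat,
                                "dec_seg")

  G$enc <- vector("list", cfg$depth + 1L)
  dcur <- de[[cfg$depth + 1L]]
  for (l in rev(seq_len(cfg$depth + 1L))) {
    bb <- block_bwd(p$enc[[l]], ca$caches$enc[[l]], dcur)
    G$enc[[l]] <- bb$grads
    if (l > 1L) {
      pl <- ca$caches$pool[[l - 1L]]
      dpool <- cpp_maxpool2_bwd(bb$dx, pl$idx, pl$H, pl$W)
      dcur <- de[[l - 1L]] + dpool
    } else {
      dx0 <- bb$dx
    }
  }
  nimg <- ca$fi_y_ch
  dfi <- dx0[, , seq_len(nimg), drop = FALSE]
  dfs <- dx0[, , nimg + seq_len(dim(dx0)[3] - nimg), drop = FALSE]
  G$blk_img <- block_bwd(p$blk_img, ca$caches$fi, dfi)$grads
  G$blk_sub <- block_bwd(p$blk_sub, ca$caches$fs, dfs)$grads
  G
}

# ---------------------------------------------------------------------------
# Optimizer and checkpoints
# ---------------------------------------------------------------------------

# Recursive elementwise walk over two parameter trees; matches children by
# name where names exist (the trees may list components in different order).
param_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
          else seq_along(a)
  for (nm in keys) {
    bb <- b[[nm]]
    if (is.null(bb)) bb <- 0
    out[[nm]] <- param_map2(f, a[[nm]], bb)
  }
  out
}

adam_init <- function(params) {
  list(m = zero_grads_like(params), v = zero_grads_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- param_map2(function(p, u) {
    if (is.integer(p)) p else p - lr * u
  }, params, upd)
  list(params = params, state = state)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration and a format version stamp.
#' @param model network; `path` file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "noncorr_net/1", model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "noncorr_net/1")) {
    stop("not a recognised checkpoint file")
  }
  obj$model
}
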