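# Shared fixtures and independent oracles used across the suite.

smooth_image <- function(d, sigma = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gaussian_smooth(array(rnorm(prod(d)), d), sigma)
}

smooth_velocity <- function(d, max_mag = 2, sigma = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- length(d)
  v <- array(rnorm(prod(d) * nd), dim = c(d, nd))
  for (k in seq_len(nd)) {
    idx <- if (nd == 2) list(quote(v[, , k])) else list(quote(v[, , , k]))
    if (nd == 2) v[, , k] <- gaussian_smooth(v[, , k], sigma)
    else v[, , , k] <- gaussian_smooth(v[, , , k], sigma)
  }
  v / max(abs(v)) * max_mag
}

# Independent flood-fill labeling oracle (BFS in plain R).
oracle_label <- function(mask, full = TRUE) {
  d <- dim(mask)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (!full) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  coords <- which(mask, arr.ind = TRUE)
  if (length(coords) == 0) return(lab)
  for (r in seq_len(nrow(coords))) {
    start <- coords[r, ]
    si <- matrix(start, 1)
    if (lab[si] != 0L) next
    cur <- cur + 1L
    queue <- list(start)
    lab[si] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        qi <- matrix(q, 1)
        if (mask[qi] && lab[qi] == 0L) {
          lab[qi] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# Brute-force surface distance oracle over boundary voxel centres.
oracle_surface <- function(pred, gt, spacing) {
  bco <- function(mask) {
    d <- dim(mask)
    nd <- length(d)
    keep <- c()
    coords <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(coords))) {
      p <- coords[r, ]
      boundary <- FALSE
      for (ax in seq_len(nd)) {
        for (s in c(-1, 1)) {
          q <- p
          q[ax] <- q[ax] + s
          if (any(q < 1) || any(q > d) || !mask[matrix(q, 1)]) boundary <- TRUE
        }
      }
      if (boundary) keep <- c(keep, r)
    }
    sweep(coords[keep, , drop = FALSE], 2, spacing, "*")
  }
  A <- bco(pred)
  B <- bco(gt)
  dmat <- as.matrix(dist(rbind(A, B)))[seq_len(nrow(A)),
                                       nrow(A) + seq_len(nrow(B)), drop = FALSE]
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  list(asd = (sum(dab) + sum(dba)) / (length(dab) + length(dba)),
       hd = max(max(dab), max(dba)))
}

# Closed-form OLS oracle via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = beta[2], r2 = 1 - ss_res / ss_tot)
}

tiny_net <- function(seed = 1, slab = 32L, base = 2L, depth = 2L,
                     slices = 3L, out_levels = 2L) {
  cfg <- network_config(in_slices = slices, base_channels = base,
                        depth = depth, out_levels = out_levels,
                        slab_height = slab, slab_width = slab)
  build_network(cfg, seed = seed)
}

small_cohort <- function(n = 2, shape = c(48, 48, 10), seed = 7,
                         p_stable = 0) {
  make_cohort(n, phantom_spec(shape), p_stable = p_stable, seed = seed,
              lesion_params = list(semi_axes_range = c(1.5, 3.5)))
}
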