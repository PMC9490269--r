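#' Dense vector-field algebra for diffeomorphic registration
#'
#' Velocity and deformation fields are numeric arrays whose last dimension
#' holds the vector components: `(H, W, 2)` in 2-D, `(H, W, D, 3)` in 3-D.
#' Components are displacements in voxel units along the corresponding array
#' axis; a deformation maps `x` to `x + u(x)`.
#'
#' @name field-algebra
NULL

field_ndim <- function(u) {
  d <- dim(u)
  nd <- length(d) - 1L
  if (!nd %in% c(2L, 3L) || d[length(d)] != nd) {
    stop("a vector field must have dim (H, W, 2) or (H, W, D, 3)")
  }
  nd
}

field_spatial_dim <- function(u) {
  d <- dim(u)
  d[-length(d)]
}

#' Zero (identity) deformation on a grid
#' @param shape spatial grid dimensions (length 2 or 3).
#' @export
identity_field <- function(shape) {
  array(0, dim = c(shape, length(shape)))
}

field_component <- function(u, k) {
  nd <- field_ndim(u)
  if (nd == 2L) u[, , k] else u[, , , k]
}

`field_component<-` <- function(u, k, value) {
  nd <- field_ndim(u)
  if (nd == 2L) u[, , k] <- value else u[, , , k] <- value
  u
}

#' Compose two deformation fields
#'
#' Returns the displacement of `phi1` after `phi2`, i.e. the field of
#' `x -> phi1(phi2(x))`: `u(x) = u2(x) + u1(x + u2(x))`, with `u1` sampled by
#' linear interpolation and replicate borders.
#'
#' @param phi1,phi2 deformation fields on the same grid.
#' @export
compose_fields <- function(phi1, phi2) {
  if (!identical(dim(phi1), dim(phi2))) {
    stop(sprintf("field shapes differ: (%s) vs (%s)",
                 paste(dim(phi1), collapse = ","),
                 paste(dim(phi2), collapse = ",")))
  }
  nd <- field_ndim(phi1)
  sdim <- field_spatial_dim(phi1)
  out <- phi2
  for (k in seq_len(nd)) {
    warped <- cpp_warp(as.double(field_component(phi1, k)),
                       as.integer(sdim), as.double(phi2), 0L)
    field_component(out, k) <- field_component(phi2, k) + warped
  }
  out
}

#' Exponentiate a stationary velocity field
#'
#' Scaling and squaring: the velocity is scaled by `2^-steps` and the
#' resulting small deformation is composed with itself `steps` times,
#' approximating the group exponential `phi = exp(v)`. The zero field maps to
#' the identity exactly, and for smooth velocities of a few voxels the result
#' has positive Jacobian determinant (a diffeomorphism on the grid).
#'
#' @param v velocity field (voxel units).
#' @param steps number of squarings (default 7, ample for displacements of a
#'   few voxels).
#' @return Deformation field (displacement from identity).
#' @export
svf_exp <- function(v, steps = 7L) {
  if (steps < 1L) stop("`steps` must be >= 1")
  if (any(!is.finite(v))) stop("velocity field contains non-finite values")
  field_ndim(v)
  u <- v / 2^steps
  for (s in seq_len(steps)) {
    u <- compose_fields(u, u)
  }
  u
}

#' Warp an image with a deformation field
#'
#' Samples `img` at `x + phi(x)` with linear or nearest-neighbour
#' interpolation; out-of-grid samples replicate the border. With linear
#' interpolation the output range cannot exceed the input range.
#'
#' @param img `image_volume` or numeric array matching the field's grid.
#' @param phi deformation field.
#' @param mode `"linear"` or `"nearest"`.
#' @export
warp_image <- function(img, phi, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  vals <- vol_values(img)
  sdim <- field_spatial_dim(phi)
  if (!identical(dim(vals), as.integer(sdim)) &&
      !identical(as.integer(dim(vals)), as.integer(sdim))) {
    stop(sprintf("image shape (%s) does not match field grid (%s)",
                 paste(dim(vals), collapse = ","),
                 paste(sdim, collapse = ",")))
  }
  out <- cpp_warp(as.double(vals), as.integer(sdim), as.double(phi),
                  if (mode == "nearest") 1L else 0L)
  vol_like(out, img)
}

# Warp returning also dL/d(img) and dL/d(phi) machinery: value plus the
# derivative of the interpolant w.r.t. the sample position.
warp_with_pos_grad <- function(img, phi) {
  vals <- vol_values(img)
  cpp_warp_grad(as.double(vals), as.integer(dim(vals)), as.double(phi))
}

# Vector-Jacobian product of warp_image (linear mode) w.r.t. both arguments:
# given gbar = dL/d(warped), returns dL/d(img) (splat) and dL/d(phi).
warp_vjp <- function(img, phi, gbar) {
  vals <- vol_values(img)
  sdim <- dim(vals)
  nd <- length(sdim)
  wg <- cpp_warp_grad(as.double(vals), as.integer(sdim), as.double(phi))
  d_img <- cpp_splat(as.double(gbar), as.integer(sdim), as.double(phi))
  d_phi <- array(0, dim = c(sdim, nd))
  pos_grad <- wg$grad
  for (k in seq_len(nd)) {
    field_component(d_phi, k) <- field_component(pos_grad, k) * gbar
  }
  list(d_img = d_img, d_phi = d_phi, value = wg$value)
}

# Forward scaling-and-squaring that keeps intermediate fields, plus the
# reverse sweep: exact adjoint of svf_exp for analytic loss gradients.
svf_exp_with_tape <- function(v, steps = 7L) {
  u <- v / 2^steps
  tape <- vector("list", steps)
  for (s in seq_len(steps)) {
    tape[[s]] <- u
    u <- compose_fields(u, u)
  }
  list(phi = u, tape = tape, steps = steps)
}

svf_exp_vjp <- function(tape_obj, gbar) {
  steps <- tape_obj$steps
  g <- gbar
  nd <- field_ndim(g)
  sdim <- field_spatial_dim(g)
  for (s in rev(seq_len(steps))) {
    u <- tape_obj$tape[[s]]
    gn <- g # direct term u_k(x)
    # interpolated term u_k(x + u_k(x)): field argument (splat) ...
    for (k in seq_len(nd)) {
      gk <- field_component(g, k)
      spl <- cpp_splat(as.double(gk), as.integer(sdim), as.double(u))
      field_component(gn, k) <- field_component(gn, k) + spl
    }
    # ... and position argument via the spatial Jacobian of the interpolant
    jac <- vector("list", nd)
    for (a in seq_len(nd)) {
      jac[[a]] <- cpp_warp_grad(as.double(field_component(u, a)),
                                as.integer(sdim), as.double(u))$grad
    }
    for (b in seq_len(nd)) {
      acc <- 0
      for (a in seq_len(nd)) {
        acc <- acc + field_component(jac[[a]], b) * field_component(g, a)
      }
      field_component(gn, b) <- field_component(gn, b) + acc
    }
    g <- gn
  }
  g / 2^steps
}

#' Spatial gradient of a scalar grid
#'
#' Central differences in the interior, one-sided differences at the borders,
#' independently along every axis. Input axes with fewer than 2 voxels are an
#' error.
#'
#' @param x `image_volume` or numeric array (2-D or 3-D scalar grid).
#' @return Array of shape `c(dim(x), n_axes)`.
#' @export
spatial_gradient <- function(x) {
  vals <- vol_values(x)
  d <- dim(vals)
  if (any(d < 2L)) stop("cannot differentiate along an axis with < 2 voxels")
  out <- array(0, dim = c(d, length(d)))
  for (ax in seq_along(d)) {
    g <- diff_axis(vals, ax)
    if (length(d) == 2L) out[, , ax] <- g else out[, , , ax] <- g
  }
  out
}

# Apply f (matrix L x m -> matrix L x m) along `axis` of an array.
axis_apply <- function(arr, axis, f) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, seq_len(nd)[-axis])
  m <- aperm(arr, perm)
  dim(m) <- c(d[axis], prod(d[-axis]))
  m <- f(m)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

diff_axis <- function(arr, axis) {
  axis_apply(arr, axis, function(m) {
    L <- nrow(m)
    out <- m
    if (L == 2L) {
      out[1, ] <- m[2, ] - m[1, ]
      out[2, ] <- m[2, ] - m[1, ]
      return(out)
    }
    out[1, ] <- m[2, ] - m[1, ]
    out[L, ] <- m[L, ] - m[L - 1, ]
    out[2:(L - 1), ] <- (m[3:L, ] - m[1:(L - 2), ]) / 2
    out
  })
}

# Adjoint of diff_axis (needed by regulariser gradients).
diff_axis_adjoint <- function(g, axis) {
  axis_apply(g, axis, function(m) {
    L <- nrow(m)
    out <- matrix(0, L, ncol(m))
    if (L == 2L) {
      out[1, ] <- -(m[1, ] + m[2, ])
      out[2, ] <- m[1, ] + m[2, ]
      return(out)
    }
    out[1, ] <- out[1, ] - m[1, ]
    out[2, ] <- out[2, ] + m[1, ]
    out[L, ] <- out[L, ] + m[L, ]
    out[L - 1, ] <- out[L - 1, ] - m[L, ]
    interior <- 2:(L - 1)
    out[interior + 1, ] <- out[interior + 1, ] + m[interior, ] / 2
    out[interior - 1, ] <- out[interior - 1, ] - m[interior, ] / 2
    out
  })
}

#' Jacobian determinant of a deformation field
#'
#' Finite-difference Jacobian of `x + u(x)`; positive everywhere for a
#' well-behaved diffeomorphism.
#'
#' @param phi deformation field.
#' @return Scalar grid of determinants.
#' @export
jacobian_determinant <- function(phi) {
  nd <- field_ndim(phi)
  sdim <- field_spatial_dim(phi)
  J <- vector("list", nd)
  for (a in seq_len(nd)) {
    J[[a]] <- spatial_gradient(field_component(phi, a))
  }
  gc <- function(a, b) {
    g <- J[[a]]
    base <- if (a == b) 1 else 0
    base + (if (nd == 2L) g[, , b] else g[, , , b])
  }
  if (nd == 2L) {
    gc(1, 1) * gc(2, 2) - gc(1, 2) * gc(2, 1)
  } else {
    gc(1, 1) * (gc(2, 2) * gc(3, 3) - gc(2, 3) * gc(3, 2)) -
      gc(1, 2) * (gc(2, 1) * gc(3, 3) - gc(2, 3) * gc(3, 1)) +
      gc(1, 3) * (gc(2, 1) * gc(3, 2) - gc(2, 2) * gc(3, 1))
  }
}
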