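# Incremental 3-D convex hull, used for the lesion convexity characteristic.
# Operating on the corner points of the mask's (boundary) voxels avoids the
# degenerate coplanar case entirely and makes a solid cube score exactly 1.

convhull_volume_3d <- function(P) {
  P <- unique(P)
  n <- nrow(P)
  if (n < 4) return(0)
  # initial tetrahedron: spread points
  i1 <- which.min(P[, 1])
  d1 <- rowSums(sweep(P, 2, P[i1, ])^2)
  i2 <- which.max(d1)
  ab <- P[i2, ] - P[i1, ]
  ap <- sweep(P, 2, P[i1, ])
  cr <- cbind(ap[, 2] * ab[3] - ap[, 3] * ab[2],
              ap[, 3] * ab[1] - ap[, 1] * ab[3],
              ap[, 1] * ab[2] - ap[, 2] * ab[1])
  i3 <- which.max(rowSums(cr^2))
  nrm <- crossp(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  h <- abs(ap %*% nrm)
  i4 <- which.max(h)
  if (h[i4] < 1e-12) return(0)
  verts <- c(i1, i2, i3, i4)
  centroid <- colMeans(P[verts, ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, orient_face, P = P, inside = centroid)
  tol <- 1e-9 * max(abs(P))
  for (pi_ in seq_len(n)) {
    if (pi_ %in% verts && length(faces) == 4) next
    p <- P[pi_, ]
    vis <- vapply(faces, function(f) {
      nrm <- attr(f, "normal")
      sum(nrm * (p - P[f[1], ])) > tol
    }, logical(1))
    if (!any(vis)) next
    # horizon: edges used exactly once among visible faces
    edges <- do.call(rbind, lapply(faces[vis], function(f) {
      rbind(sort(c(f[1], f[2])), sort(c(f[2], f[3])), sort(c(f[1], f[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[!vis]
    for (e in seq_len(nrow(horizon))) {
      f <- orient_face(c(horizon[e, ], pi_), P, centroid)
      faces[[length(faces) + 1]] <- f
    }
  }
  vol <- 0
  for (f in faces) {
    a <- P[f[1], ] - centroid
    b <- P[f[2], ] - centroid
    cc <- P[f[3], ] - centroid
    vol <- vol + abs(sum(a * crossp(b, cc))) / 6
  }
  vol
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

orient_face <- function(f, P, inside) {
  nrm <- crossp(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
  if (sum(nrm * (inside - P[f[1], ])) > 0) {
    f <- c(f[1], f[3], f[2])
    nrm <- -nrm
  }
  attr(f, "normal") <- nrm
  f
}

# Convex hull volume of a voxel set (logical mask), using the corner points
# of its 26-boundary voxels scaled by the physical spacing.
mask_hull_volume <- function(mask, spacing = rep(1, length(dim(mask)))) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(0)
  coords <- arrayInd(idx, d)
  if (length(d) == 2L) coords <- cbind(coords, 1L)
  # boundary voxels: any missing neighbour in the 26-neighbourhood
  interior <- erode_mask(mask, sqrt(3) + 1e-6)
  bidx <- which(mask & !interior)
  if (length(bidx) == 0) bidx <- idx
  bc <- arrayInd(bidx, d)
  if (length(d) == 2L) bc <- cbind(bc, 1L)
  offs <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  pts <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o) {
    sweep(bc, 2, offs[o, ], "+")
  }))
  sp3 <- if (length(spacing) == 2L) c(spacing, 1) else spacing
  pts <- sweep(pts, 2, sp3, "*")
  convhull_volume_3d(pts)
}
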