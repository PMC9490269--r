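#' Image volume with physical voxel spacing
#'
#' A thin container for a dense scalar grid. The first two array axes are the
#' in-plane (axial) directions, the third (if present) indexes slices.
#' Spacing is in millimetres per voxel; displacements elsewhere in the package
#' are expressed in voxel units, so spacing only enters volume (mm^3) and
#' surface-distance computations.
#'
#' @param values numeric array, 2-D or 3-D, finite.
#' @param spacing positive numeric vector, one entry per array axis (mm).
#' @param origin physical offset of the first voxel (mm).
#' @return An object of class `image_volume` with fields `values`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(values, spacing = rep(1, length(dim(values))),
                         origin = rep(0, length(dim(values)))) {
  if (is.null(dim(values))) stop("`values` must be a 2-D or 3-D array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("`values` must have 2 or 3 dimensions")
  if (length(spacing) != nd) stop("`spacing` must have one entry per axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be strictly positive on all axes")
  }
  if (any(!is.finite(values))) stop("`values` contains non-finite entries")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

# Accept either an image_volume or a bare array; return the array.
vol_values <- function(x) {
  if (is_image_volume(x)) x$values else x
}

vol_spacing <- function(x, default = NULL) {
  if (is_image_volume(x)) return(x$spacing)
  if (!is.null(default)) return(default)
  rep(1, length(dim(x)))
}

# Rebuild a result with the metadata of a template input.
vol_like <- function(values, template) {
  if (is_image_volume(template)) {
    image_volume(values, template$spacing, template$origin)
  } else {
    values
  }
}
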