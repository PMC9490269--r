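#' NIfTI input / output and cohort handling
#'
#' Volumes are read with RNifti and reoriented to a fixed RAS convention, so
#' "axial slices" are unambiguously the planes indexed by the third array
#' axis. Masks are written as uint8, probabilistic maps as float32.
#'
#' @name io
NULL

#' Read a NIfTI volume
#'
#' @param path NIfTI-1/2 file.
#' @param resample_iso optional isotropic target spacing in mm; linear
#'   interpolation for images, nearest for masks.
#' @param mask read as a binary mask (nearest-neighbour resampling).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, resample_iso = NULL, mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  ort <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(ort, "try-error") && !is.na(ort) && nzchar(ort) &&
      ort != "RAS") {
    ok <- try({
      RNifti::orientation(img) <- "RAS"
    }, silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop(sprintf("cannot determine orientation of %s: missing affine?",
                   path))
    }
  }
  vals <- as.array(img)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- abs(pd[seq_along(dim(vals))])
  vals <- array(as.numeric(vals), dim(vals)) # strip NIfTI attributes
  vol <- image_volume(vals, spacing)
  if (!is.null(resample_iso)) {
    vol <- resample_volume(vol, rep(resample_iso, length(dim(vals))),
                           mode = if (mask) "nearest" else "linear")
  }
  if (mask) vol$values <- (vol$values > 0.5) * 1
  vol
}

#' Write a volume as NIfTI
#'
#' @param vol [image_volume()], or an array with unit spacing.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; masks should use `"uint8"`,
#'   probability maps `"float"`.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  if (!is_image_volume(vol)) vol <- image_volume(vol)
  nii <- RNifti::asNifti(vol$values)
  RNifti::pixdim(nii) <- vol$spacing
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

# Linear (or nearest) resampling along one axis to a new length.
axis_resample <- function(arr, axis, new_n, mode = "linear") {
  axis_apply_len <- function(arr, axis, f, new_len) {
    d <- dim(arr)
    nd <- length(d)
    perm <- c(axis, seq_len(nd)[-axis])
    m <- aperm(arr, perm)
    dim(m) <- c(d[axis], prod(d[-axis]))
    m <- f(m)
    dn <- d[perm]
    dn[1] <- new_len
    dim(m) <- dn
    aperm(m, order(perm))
  }
  axis_apply_len(arr, axis, function(m) {
    L <- nrow(m)
    if (new_n == L) return(m)
    pos <- seq(0, L - 1, length.out = new_n)
    if (mode == "nearest") {
      return(m[pmin(pmax(round(pos) + 1, 1), L), , drop = FALSE])
    }
    i0 <- pmin(floor(pos), L - 2)
    f <- pos - i0
    m[i0 + 1, , drop = FALSE] * (1 - f) + m[i0 + 2, , drop = FALSE] * f
  }, new_n)
}

#' Resample a volume to a new spacing
#'
#' @param vol [image_volume()].
#' @param new_spacing target spacing per axis (mm).
#' @param mode `"linear"` or `"nearest"` (masks).
#' @export
resample_volume <- function(vol, new_spacing, mode = "linear") {
  d <- dim(vol$values)
  new_d <- pmax(round(d * vol$spacing / new_spacing), 2)
  vals <- vol$values
  for (ax in seq_along(d)) {
    if (new_d[ax] != d[ax]) vals <- axis_resample(vals, ax, new_d[ax], mode)
  }
  image_volume(vals, new_spacing, vol$origin)
}

#' Export a deformation field as a multi-component NIfTI
#'
#' Stores the components in the last dimension for inspection in external
#' viewers.
#' @param field displacement field; `path` output file.
#' @export
write_field <- function(field, path) {
  nii <- RNifti::asNifti(field)
  RNifti::writeNifti(nii, path, datatype = "float")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohorts on disk
# ---------------------------------------------------------------------------

#' Write a phantom cohort to a directory
#'
#' One sub-directory per patient with baseline / follow-up / brain-mask /
#' ground-truth NIfTIs plus a cohort `manifest.json`.
#'
#' @param cohort list of cases (see [make_cohort()]).
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(cs) {
    pdir <- file.path(dir, cs$id)
    dir.create(pdir, showWarnings = FALSE)
    write_volume(cs$baseline, file.path(pdir, "baseline.nii.gz"))
    write_volume(cs$follow_up, file.path(pdir, "follow_up.nii.gz"))
    write_volume(image_volume(cs$brain_mask * 1, cs$baseline$spacing),
                 file.path(pdir, "brain_mask.nii.gz"), datatype = "uint8")
    write_volume(image_volume(cs$gt_lesion_mask * 1, cs$baseline$spacing),
                 file.path(pdir, "ground_truth.nii.gz"), datatype = "uint8")
    list(id = cs$id, baseline = file.path(cs$id, "baseline.nii.gz"),
         follow_up = file.path(cs$id, "follow_up.nii.gz"),
         brain_mask = file.path(cs$id, "brain_mask.nii.gz"),
         ground_truth = file.path(cs$id, "ground_truth.nii.gz"),
         stable = isTRUE(cs$stable))
  })
  manifest <- list(schema = "noncorreg-cohort/1",
                   spacing = cohort[[1]]$baseline$spacing,
                   patients = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Loads the volumes referenced by `manifest.json` and recomputes candidate
#' masks for training.
#'
#' @param dir cohort directory written by [write_cohort()] (or following the
#'   same per-patient layout).
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  pats <- mf$patients
  cohort <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    B <- read_volume(file.path(dir, p$baseline))
    F_ <- read_volume(file.path(dir, p$follow_up))
    bm <- read_volume(file.path(dir, p$brain_mask), mask = TRUE)$values > 0
    gt <- if (!is.na(p$ground_truth) && nzchar(p$ground_truth) &&
              file.exists(file.path(dir, p$ground_truth))) {
      read_volume(file.path(dir, p$ground_truth), mask = TRUE)$values > 0
    } else {
      array(FALSE, dim(B$values))
    }
    cohort[[i]] <- list(id = p$id, baseline = B, follow_up = F_,
                        brain_mask = bm, gt_lesion_mask = gt,
                        candidate = candidate_mask(B, F_, bm, bm),
                        stable = isTRUE(p$stable))
  }
  cohort
}

#' Write per-patient and cohort reports
#'
#' Writes a CSV and a JSON file carrying identical numbers; the last row is
#' the cohort summary.
#'
#' @param df data frame from [summarize_cohort()] (or any per-patient table).
#' @param path_base path without extension; `.csv` / `.json` are appended.
#' @export
write_report <- function(df, path_base) {
  csv <- paste0(path_base, ".csv")
  json <- paste0(path_base, ".json")
  write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(list(schema = "noncorreg-report/1", rows = df),
                       json, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(c(csv = csv, json = json))
}

# ---------------------------------------------------------------------------
# Plain key/value configuration
# ---------------------------------------------------------------------------

#' Read a plain `key: value` configuration file
#'
#' Lines starting with `#` are ignored; values are auto-typed (logical,
#' numeric, comma-separated numeric vectors, otherwise strings). Precedence
#' elsewhere is CLI flag > config file > built-in default.
#'
#' @param path file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (toupper(val) %in% c("TRUE", "FALSE")) return(as.logical(toupper(val)))
  parts <- trimws(strsplit(val, ",")[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) return(if (length(nums) == 1) nums[1] else nums)
  val
}
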