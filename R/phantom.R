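#' Synthetic longitudinal FLAIR-like phantoms
#'
#' Deliberately simple geometric phantoms (nested ellipsoidal tissue shells
#' with a dark ventricle, smooth intensity variation and noise) that exercise
#' the intensity-threshold logic, masking, registration and lesion machinery
#' without any external data. They emulate the statistics that matter for the
#' method — hyperintense compact new lesions on a smooth background, dark
#' CSF, a closed brain mask — not anatomy.
#'
#' @name phantom
NULL

#' Phantom specification
#'
#' @param shape grid size (in-plane, in-plane, slices).
#' @param spacing voxel size in mm (default 1 mm isotropic so voxel counts
#'   equal mm^3).
#' @param noise_sigma additive Gaussian noise level (intensity units; the
#'   tissue means are of order 0.5).
#' @param smooth_sigma sigma of the smooth intensity variation field.
#' @export
phantom_spec <- function(shape = c(96, 96, 24), spacing = c(1, 1, 1),
                         noise_sigma = 0.02, smooth_sigma = 12) {
  stopifnot(length(shape) == 3, all(shape[1:2] >= 16), shape[3] >= 4)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 noise_sigma = noise_sigma, smooth_sigma = smooth_sigma),
            class = "phantom_spec")
}

#' Generate one phantom head
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the phantom is reproducible from (spec, seed).
#' @return List with `volume` (`image_volume`) and `brain_mask` (logical,
#'   one connected ellipsoid). Ventricle voxels have normalized intensity
#'   below 0.1 so the candidate mask excludes them.
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L) {
  set.seed(seed)
  d <- spec$shape
  ii <- (slice_index(d, 1) - (d[1] + 1) / 2) / (d[1] / 2)
  jj <- (slice_index(d, 2) - (d[2] + 1) / 2) / (d[2] / 2)
  kk <- (slice_index(d, 3) - (d[3] + 1) / 2) / (d[3] / 2)
  # brain ellipsoid and nested shells
  r_brain <- sqrt((ii / 0.82)^2 + (jj / 0.9)^2 + (kk / 0.85)^2)
  brain <- r_brain <= 1
  vals <- array(0.02, dim = d)       # background "air"
  vals[brain] <- 0.55                # white matter-ish plateau
  gm <- brain & r_brain > 0.75       # brighter cortical rim
  vals[gm] <- 0.7
  # dark ventricle: small central ellipsoid, intensity below the 0.1
  # normalized threshold
  r_vent <- sqrt((ii / 0.18)^2 + ((jj + 0.08) / 0.25)^2 + (kk / 0.35)^2)
  vent <- r_vent <= 1
  vals[vent] <- 0.02
  # smooth intensity variation + noise
  sm <- gaussian_smooth(array(rnorm(prod(d)), d), spec$smooth_sigma)
  sm <- sm / max(abs(sm), 1e-12) * 0.05
  vals[brain] <- vals[brain] + sm[brain]
  vals <- vals + array(rnorm(prod(d), sd = spec$noise_sigma), d)
  vals <- pmax(vals, 0)
  list(volume = image_volume(vals, spec$spacing), brain_mask = brain,
       ventricle = vent)
}

#' Generate one longitudinal case
#'
#' Baseline is a phantom; the follow-up is the baseline with simulated new
#' lesions inserted (progressive case) or not (stable case), then elastically
#' deformed. The ground-truth new-lesion mask lives in follow-up space (the
#' inserted mask warped with the ground-truth deformation).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param stable if TRUE no lesions are inserted (a stable patient).
#' @param lesion_params list passed on to [insert_lesions()].
#' @param elastic_amplitude,elastic_smoothing elastic deformation settings
#'   (voxels); amplitude 0 disables the deformation.
#' @return List with `baseline`, `follow_up` (`image_volume`s),
#'   `brain_mask`, `gt_lesion_mask`, `gt_field`, `lesions`, `stable`.
#' @export
make_longitudinal_case <- function(spec = phantom_spec(), seed = 1L,
                                   stable = FALSE, lesion_params = list(),
                                   elastic_amplitude = 2,
                                   elastic_smoothing = 8) {
  ph <- make_phantom(spec, seed = seed)
  set.seed(seed + 1000003L)
  B <- ph$volume
  d <- dim(B$values)
  cand <- candidate_mask(B, B, ph$brain_mask, ph$brain_mask)
  if (stable) {
    lesioned <- B$values
    lmask <- array(FALSE, d)
    lesions <- NULL
  } else {
    ins <- do.call(insert_lesions, c(list(img = B$values, cand = cand),
                                     lesion_params))
    lesioned <- ins$image
    lmask <- ins$mask
    lesions <- ins$lesions
  }
  if (elastic_amplitude > 0) {
    el <- elastic_deform(lesioned, amplitude = elastic_amplitude,
                         smoothing = elastic_smoothing)
    fu_vals <- vol_values(el$image)
    gt_field <- el$field
    gt_mask <- array(cpp_warp(as.double(lmask * 1), as.integer(d),
                              as.double(gt_field), 1L) > 0.5, d)
  } else {
    fu_vals <- lesioned
    gt_field <- identity_field(d)
    gt_mask <- lmask
  }
  list(baseline = B,
       follow_up = image_volume(fu_vals, spec$spacing),
       brain_mask = ph$brain_mask,
       candidate = cand,
       gt_lesion_mask = gt_mask,
       gt_field = gt_field,
       lesions = lesions,
       stable = stable)
}

#' Generate a phantom cohort
#'
#' @param n number of cases.
#' @param spec a [phantom_spec()].
#' @param p_stable probability that a case has no new lesions.
#' @param seed cohort seed; case seeds are derived deterministically.
#' @param ... passed to [make_longitudinal_case()].
#' @return List of cases (see [make_longitudinal_case()]), each with an `id`.
#' @export
make_cohort <- function(n = 10L, spec = phantom_spec(), p_stable = 0.5,
                        seed = 1L, ...) {
  set.seed(seed)
  stable_flags <- runif(n) < p_stable
  case_seeds <- sample.int(2^30, n)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- make_longitudinal_case(spec, seed = case_seeds[i],
                                 stable = stable_flags[i], ...)
    cs$id <- sprintf("case%03d", i)
    cohort[[i]] <- cs
  }
  cohort
}
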