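---
title: "Joint registration, non-correspondence segmentation and lesion appearance modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint registration, non-correspondence segmentation and lesion appearance modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noncorreg)
```

## The problem

Monitoring multiple sclerosis hinges on finding *newly formed* lesions
between a baseline and a follow-up FLAIR MR scan. Registering the two scans
first and comparing them afterwards is self-defeating: a good registration
will happily deform old structures until the new lesion has been "explained
away". `noncorreg` instead couples the two problems. A single model
produces, for a rigidly pre-aligned pair (baseline $B$, follow-up $F$):

* a **diffeomorphic deformation** $\varphi = \exp(v)$, the group
  exponential of a stationary velocity field $v$, which aligns everything
  that *does* correspond (old lesions changing size, global misalignment);
* a **non-correspondence map** $N \in [0,1]$ marking regions with no
  counterpart in the baseline — new lesions;
* **appearance offsets** $A \in \mathbb{R}$, an additive intensity field
  that, masked by $N$, synthesizes the new lesion's intensity on the
  baseline.

Two objectives drive this. The unsupervised form masks the image distance
with $1-N$:

$$\mathcal{L}_{NCR} = (1-N)\cdot D(F, B\circ\varphi) + \alpha R_\varphi + \beta R_N,$$

with $R_\varphi = \lVert\nabla v\rVert_2^2$ and
$R_N = \Sigma_x N + \gamma\,\tanh(\lVert\nabla N\rVert_2)$ keeping the
velocity smooth and the segmentation small and regularly bordered. The
supervised form composites the appearance change into the moving image and
replaces the mask regularizer with a Dice term against a ground-truth
new-lesion segmentation $S$:

$$\mathcal{L} = D\!\left(F, (B + N\cdot A)\circ\varphi\right) + \alpha R_\varphi + \beta\,\mathcal{L}_{Dice}(N\circ\varphi, S).$$

$D$ is a normalized-cross-correlation distance, $1-\mathrm{NCC}^2$,
evaluated over local windows (default edge length 9) so that smooth
intensity bias between visits does not masquerade as change; a global
variant is available. Both objectives, all regularizers and their exact
analytic gradients are implemented in `R/losses.R` and verified against
finite differences to a relative error below $10^{-3}$.

## Model and inference

The network (`build_network()`) is a compact U-Net with one encoder and two
decoders. Baseline and follow-up slabs pass through one initial
convolutional block and their subtraction image through a second; the
concatenated features descend through max-pooling stages with channel
doubling, and each decoder ascends with skip connections. One decoder emits
the in-plane velocity field, the other the sigmoid-bounded $N$ and linear
$A$. Outputs appear at the three finest resolutions and the loss is a
weighted sum over levels with weights $0.7, 0.2, 0.1$, finest first
(deep supervision).

Input is 2.5-D: a stack of `in_slices = 5` axial slices (nominally
$368 \times 512$ after isotropic resampling; any size divisible by
$2^{depth}$ works). At inference `segment_volume()` iterates slice-wise and
keeps the central-slice prediction, producing one output slice per input
slice. Fold models from `crossval_split()` can be ensembled; binarized maps
are combined by per-voxel majority vote (ties broken positive). Every
surviving component smaller than 3 mm³ is discarded and the result is
multiplied with the brain mask (`postprocess()`); a 3 mm³ component is
*not* smaller than 3 mm³ and is kept.

Because no deep-learning framework is assumed, the forward and backward
passes are written directly against compiled im2col/GEMM kernels
(`src/ops.cpp`), and the chain rule through warping and through the
scaling-and-squaring exponential is implemented as exact adjoints of the
forward interpolation code. This is what makes the finite-difference
gradient checks meaningful: they validate the same code path used for
training.

## Geometry choices

* Displacements are stored in **voxel units** on the native grid; physical
  spacing (mm) enters only volume and surface-distance computations.
* $\exp(v)$ uses scaling and squaring with 7 squarings by default — ample
  for displacements of a few voxels (doubling the steps moves the result by
  far less than 0.1 voxel).
* Interpolation is bilinear/trilinear with **replicate borders**, which
  avoids injecting background zeros at the brain edge; nearest-neighbour is
  used for masks.
* All geometry operations run in 2-D (per-slab network fields) and 3-D
  (simulator and evaluation).

## Training protocol

Pre-training addresses the extreme rarity of new lesions by synthesizing
them. From a lesion-free baseline the simulator builds a candidate-location
mask: the union of the two brain masks, thresholded above 0.1 of the
min-max-normalized intensity of both images (this removes the dark
ventricles), then shrunk by a ball erosion (radius 2 voxels) so lesions
cannot protrude from the brain. One to five Gaussian-ellipsoid lesions are
added at uniformly drawn candidate locations; a random in-plane elastic
deformation (Gaussian-smoothed noise field) then produces the fixed image,
the original serving as moving image. The loss is Dice on the simulated
mask plus the mean squared error between the predicted and the known
deformation, deep-supervised. Defaults reflect the full-scale protocol: 200
epochs, Adam, learning rate $10^{-4}$ decayed by 0.8 every 20 epochs.
Fine-tuning then minimizes the appearance objective for 400 epochs with an
exponentially decaying rate, drawing only slabs whose central slice
intersects the ground-truth lesion mask and passing each slab twice, once
flipped horizontally. Six augmentations are available and applied with
configurable probabilities: Gaussian noise, brightness change and a
brightness gradient (brain-restricted, per image), adaptive histogram
equalization, and a rotation within ±5° / in-plane shift within ±3 px
applied identically to both images and to ground-truth fields and masks.

Two numerical choices in the training loop deserve explanation:

* **Ellipsoid profile.** The added intensity is
  $a\,(e^{-q/2} - \ell)_+/(1-\ell)$ with iso-level $\ell = 0.5$: the
  classic Gaussian bump, shifted and truncated at its half-maximum contour
  and rescaled back to peak $a$. The lesion mask is therefore exactly the
  support of the added intensity — the simulated pair differs from the
  deformed baseline *only* inside the recorded mask, which is the invariant
  the evaluation relies on. Semi-axes are drawn from $[1.5, 5]$ voxels and
  peaks from $[0.3, 0.7]$ of the robust (1st–99th percentile) intensity
  range: new MS lesions are small and clearly hyperintense on FLAIR.
* **Segmentation stabilizer.** Soft Dice under a ~0.3 % foreground
  fraction has a well-known failure mode: the quickest descent direction is
  "predict background everywhere", and once the sigmoid saturates the Dice
  gradient vanishes and training never recovers. The training loops
  therefore add a positively-weighted cross-entropy term *on the logits*
  (weight `seg_stabilizer`, default 1), whose gradient $N - S$ does not
  vanish under saturation. The reported objectives are unchanged; setting
  `seg_stabilizer = 0` trains on the bare loss. A quarter of pre-training
  slabs are left lesion-free (`p_negative`) so the model also sees
  deformation-only negatives and learns to suppress false positives.

## The phantom cohort

`make_phantom()` builds deliberately simple heads: an ellipsoidal brain
with a brighter cortical rim, a dark central ventricle (below the 0.1
candidate threshold by construction), a smooth intensity variation field
and Gaussian noise, at 1 mm isotropic spacing so voxel counts equal mm³.
`make_cohort()` pairs each baseline with a follow-up that is elastically
deformed and, for progressive cases, lesioned first; stable cases
(probability `p_stable`, default 0.5) stay lesion-free. The phantoms
exercise exactly what the method needs — threshold logic, masking,
registration, compact hyperintense lesions, class imbalance — and nothing
they do not: there is no MR physics, no anatomy, no multi-site intensity
variation. Passing the recovery study on phantoms demonstrates that the
pipeline is wired correctly and can learn its task end-to-end; it does not
certify performance on clinical data.

## Evaluation suite

All analyses are lesion-level first: connected components under
26-connectivity (the in-plane + through-plane neighbourhood standard for
3-D lesions; the connectivity is a config switch). A ground-truth
lesion is *detected* if it shares at least one voxel with a predicted
lesion — the common convention in the MS literature; stricter minimum
overlaps are available. From the matching follow lesion sensitivity,
positive predictive value and their harmonic mean F1 (zero when both are
zero); for lesion-free patients the count and volume of false lesions and
the stable flag `det_s`; for lesioned patients the progressing flag
`det_p`. Voxel metrics are Dice, average symmetric surface distance and
Hausdorff distance over boundary voxel centres (a boundary voxel has a face
neighbour outside the mask), in mm; empty-vs-nonempty cases report Dice 0
with flagged, absent distances. Lesion-wise Dice averages per ground-truth
lesion against the union of overlapping predictions, over all or over
detected lesions only. Cohort numbers are arithmetic means over patients,
never voxel-pooled.

Per-lesion characteristics follow their stated formulas: cube root of the
volume as a diameter proxy; convexity as lesion volume over convex-hull
volume (computed on the corner points of boundary voxels, which makes a
solid cube score exactly 1 and sidesteps degenerate coplanar point sets);
contrast to the surrounding tissue from the mean follow-up intensities
inside the lesion versus a 2-voxel dilated shell, as difference over mean;
and contrast to baseline analogously against the in-lesion baseline mean.
`trimmed_regression()` relates any characteristic to per-lesion Dice by
ordinary least squares after discarding lesions outside the 5th–95th
percentile of the characteristic, reporting slope and $R^2$.

## Problem sizes and the scaled-down study

The full protocol (whole-head volumes, 368×512 slabs, 200 + 400 epochs,
five-fold ensembling) is a GPU-scale computation. The package's own
end-to-end study — run by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` — uses a 10-case phantom cohort at 96×96×24,
8 base channels, 20 pre-training epochs (3 slabs per case, learning rate
$10^{-3}$) and 20 fine-tuning epochs (1 lesion slab per case, passed twice
with the horizontal flip, rate $5\times10^{-4}$). The larger learning rates
compensate for the short schedule of the much smaller model. Fine-tuning
applies the package's checkpoint-selection rule: one progressive and one
stable case are held out, and every fourth epoch the mean lesion-level F1
minus a small false-lesion penalty is evaluated on them; the best-scoring
checkpoint (the incoming pre-trained model competes too) is returned.
Because fine-tuning deliberately samples only lesion-bearing slabs, long
fine-tuning runs can drift toward over-segmentation on unseen slices;
validation selection is what keeps the false-lesion count low. On one CPU
core this trains in a few minutes and recovers, after postprocessing, at
least 80 % of simulated lesions of at least 8 voxels with at most 2 false
lesions per case, and instance-wise optimization of the appearance
objective on a single pair reduces the mean absolute in-lesion residual
between follow-up and adapted baseline by more than half.

## Known limitations

* The phantom generator makes no claim of anatomical or radiometric
  realism; conclusions about clinical data require real cohorts.
* Brain extraction is out of scope — masks are supplied by the user (or by
  the phantom generator).
* Velocity fields are per-slab and in-plane at network level; fully 3-D
  deformation decoding is not implemented.
* Time-varying velocity fields (LDDMM), B-spline transforms and
  mutual-information distances are non-goals.
* The loss weights $\alpha$, $\beta$, $\gamma$ have no canonical reference
  values; the defaults here are 1 and fully configurable.
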