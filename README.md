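# noncorreg

Joint diffeomorphic registration and new-lesion analysis for longitudinal
FLAIR MRI of multiple sclerosis.

Registering a baseline brain scan to its follow-up and *then* looking for
change is self-defeating: a good registration deforms old structures until
genuinely new lesions have been explained away. `noncorreg` couples the two
problems. One model jointly estimates, for a rigidly pre-aligned pair
(baseline `B`, follow-up `F`):

* a **diffeomorphic deformation** `φ = exp(v)` (scaling-and-squaring
  exponential of a stationary velocity field) aligning everything that does
  correspond,
* a **non-correspondence segmentation** `N ∈ [0,1]` marking newly formed
  lesions, and
* **appearance offsets** `A`, an additive intensity field that — masked by
  `N` — models the new lesion's intensity on the baseline.

Training minimizes either the unsupervised masked-distance objective

```
L = (1 − N) · D(F, B∘φ) + α‖∇v‖² + β·(Σx N + γ·tanh(‖∇N‖₂))
```

or, with a ground-truth new-lesion mask `S`, the supervised
appearance-adaptation objective

```
L = D(F, (B + N·A)∘φ) + α‖∇v‖² + β·Dice(N∘φ, S)
```

with a local normalized-cross-correlation distance `D = 1 − NCC²` and deep
supervision over three resolutions (weights 0.7 / 0.2 / 0.1). The package
contains the full surrounding machinery: the two-decoder 2.5-D network with
hand-written, finite-difference-verified backpropagation; the lesion
simulator used for pre-training (candidate masks, Gaussian-ellipsoid
insertion, elastic deformations, intensity augmentations); a phantom cohort
generator so everything runs without external data; slice-slab inference
with majority-vote ensembling and the 3 mm³ minimum-volume filter; and the
lesion-level evaluation suite (sensitivity, PPV, F1, surface distances,
lesion-wise Dice, lesion characteristics, percentile-trimmed regression).

It is aimed at researchers in longitudinal lesion analysis who want an
inspectable, dependency-light reference implementation of joint
registration + non-correspondence modeling.

## Worked example

Simulate a longitudinal case with known new lesions, model the lesions by
instance-wise optimization of the appearance objective on one slice, and
score the simulator's ground truth:

```r
library(noncorreg)

cs <- make_longitudinal_case(phantom_spec(c(96, 96, 24)), seed = 7)
k  <- which(apply(cs$gt_lesion_mask, 3, any))[1]  # a lesion-bearing slice
B  <- cs$baseline$values[, , k]
F_ <- cs$follow_up$values[, , k]
S  <- cs$gt_lesion_mask[, , k] * 1

opt <- instance_optimize(F_, B, S, iters = 200, steps = 4)
lesion <- S > 0
c(before = mean(abs((F_ - B)[lesion])),
  after  = mean(abs((F_ - opt$adapted)[lesion])))
#>      before       after
#> 0.024693619 0.008861407

r <- evaluate_patient(opt$N > 0.5, S)
c(f1 = r$detection$f1, dice = r$overlap$dice)
#>   f1 dice
#>    1    1
```

The optimized non-correspondence map recovers the simulated lesion exactly
on this slice (lesion-level F1 = 1, voxel Dice = 1), and the adapted
baseline `(B + N·A)∘φ` reproduces the follow-up inside the lesion: the
mean in-lesion residual drops from 0.0247 to 0.0089 intensity units, a
reduction of about 64 %. The same quantities are
produced at cohort scale by the trained network via `pretrain()`,
`finetune()`, `segment_volume()` and `postprocess()`.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "noncorreg", package = "noncorreg")` with subcommands
`phantom`, `simulate`, `pretrain`, `train`, `segment`, `evaluate` and
`model-lesions`, each accepting `--seed` for bit-reproducible runs.

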