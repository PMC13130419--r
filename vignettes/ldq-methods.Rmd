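---
title: "Quantifying lumbar-spine intramuscular fat from Dixon MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lumbar-spine intramuscular fat from Dixon MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Intramuscular fat (IMF) in the lumbar muscles — psoas (P), iliacus (I),
quadratus lumborum (QL) and the erector spinae + multifidus complex (ESM) —
is a biomarker of muscle degeneration and sarcopenia. Dixon MRI separates
each voxel's signal into water (W) and fat (F) channels, with the in-phase
image IP = W + F, so the proton-density fat fraction

\[ \mathrm{FF} = \frac{F}{W + F} \]

can be measured per voxel and summarised per muscle once a 3D mask of the
muscle exists. The bottleneck is segmentation: manual 3D delineation of
eight bilateral compartments takes hours per scan. `ldq` implements an
automated pipeline around a 3D U-Net segmentation engine, with a
multi-atlas baseline, fat-fraction quantification, and the statistical
layer needed to turn per-subject measurements into normative reference
tables.

Because clinical Dixon cohorts cannot be redistributed, the package ships a
synthetic Dixon phantom generator that serves as a fully controlled test
bed. All package tests and the acceptance script run end-to-end on
phantoms; no clinical data is required.

## The phantom: what it emulates and what it does not

`phantom_spec()` describes a two-compartment (water/fat) anatomy on a
64 x 64 x 32 grid at 2 x 2 x 3 mm (configurable up to full scan
resolution). Inside every structure the proton density \(\rho\) is split as
\(F = \mathrm{FF}\,\rho\), \(W = (1-\mathrm{FF})\,\rho\). The scene contains:

* eight elliptical muscle tubes with per-muscle generative FF (defaults
  P 15%, I 11.5%, QL 14.5%, ESM 22%, central values of healthy-adult
  normative ranges), unit proton density;
* interstitial body tissue (\(\rho = 0.7\), FF 0.3) — the lower density
  makes muscle boundaries visible on the in-phase image, as in real scans;
* a subcutaneous fat ring (FF 0.9) and, optionally, a thin epimuscular fat
  shell posterior to ESM that is deliberately *not* part of the muscle
  label, to exercise the exclusion of epimuscular fat from masks;
* background anatomy of the lumbar field of view: a low-density vertebral
  body on the midline and the two great vessels — aorta left of midline,
  the larger inferior vena cava right of it. The vessels matter: without
  them the phantom would be perfectly mirror-symmetric and the left/right
  assignment of compartments would be learnable only through image-border
  effects. Real anatomy is not mirror-symmetric, and the phantom follows.

Inter-subject variability comes from a smooth random displacement field
(Gaussian-filtered white noise, default amplitude 3 mm, correlation length
12 mm). The field is *not* applied by resampling a rasterised image:
instead each voxel centre \(x\) is classified by the analytic anatomy
evaluated at \(x + u(x)\). Channels and labels therefore deform through the
identical mapping and stay exactly consistent — with zero noise, the mean
FF inside every ground-truth mask equals the generative FF to machine
precision at any deformation amplitude, which makes FF-recovery tests
sharp. The price is the absence of partial-volume mixing at tissue borders;
this is the main respect (besides simplified geometry, Gaussian rather
than Rician noise, and the absence of bias fields and chemical-shift
artifacts) in which passing phantom tests does not certify behaviour on
real data.

Channel noise is zero-mean Gaussian (default sd 0.02 on a unit-density
scale), applied independently to W and F and clipped at zero; IP is formed
afterwards so IP = W + F holds voxel-wise by construction.

`cohort_spec()`/`generate_cohort()` add the population layer: per subject
and muscle,

\[ \mathrm{FF} = \beta_0 + \beta_{age}(age-40) + \beta_{sex}\,male +
   \beta_{BMI}(BMI-25) + \beta_{act}\,active + \varepsilon, \]

clipped to [0.01, 0.95], both sides sharing the value up to an optional
asymmetry term. Default effect directions and magnitudes emulate a healthy
adult cohort (FF rises with age, falls with physical activity, ESM highest,
iliacus lowest; males lower ESM FF); covariates are drawn as uniform age
20–70 y, Bernoulli sex, Gaussian BMI 25.7 ± 5.6 kg/m² truncated to
[16, 45], Bernoulli activity group.

## Homogenisation and augmentation

`homogenise()` rigid-registers every subject's in-phase image to a
reference (first id in sort order unless configured), resamples all
channels linearly (labels nearest-neighbour) onto the reference lattice and
downsamples in-plane by a factor of 2 — block averaging for images
(anti-aliased), block mode with lowest-code tie-break for labels. A factor
of 2 turns 0.47 x 0.47 x 1.95 mm voxels into 0.94 x 0.94 x 1.95 mm and
cuts the voxel count four-fold.

Training-set augmentation has two arms, planned explicitly
(`augment_plan()`) so leakage can be checked structurally:

* **Linear** (`linear_plan()`): each training image contributes
  {unflipped, flipped} x {0°, ±5°, ±10°} = 10 variants. The identity
  rotation is included in both the unflipped and flipped sets — this is
  the only reading under which 18 training subjects yield exactly 180
  linear images. Flips mirror across the medial-lateral (x) axis and swap
  left/right label codes; rotations are in-plane (about the slice axis) by
  default, modelling patient-positioning variability, with the rotation
  axis configurable since either convention is defensible.
* **Nonlinear** (`nonlinear_plan()`, `synthesize_deformed()`): one record
  per ordered pair of distinct training subjects — n(n−1) records, 306
  for n = 18 — realised by *early-stopped* B-spline registration of the
  moving image toward the fixed one. Stopping the optimisation well before
  convergence leaves the warped image between the two anatomies: a
  "virtual anatomy" that injects realistic variability. The moving labels
  are propagated through the same transform (nearest-neighbour).

With both arms, 18 training subjects yield 180 + 306 = 486 images.
`assert_no_leakage()` fails hard if any plan record references a
validation subject directly or as a registration partner.

## The registration engine

No registration backend exists for R in this package's dependency set, so
`ldq` implements its own, honouring a backend-agnostic contract:
normalised cross-correlation (NCC) similarity, a stochastic gradient
optimiser with decaying gain (the adaptive stochastic gradient descent
family: random voxel samples each iteration, gain
\(a_k = a (A+1)^{0.602}/(A+1+k)^{0.602}\)), and a Gaussian image pyramid.
Three transform stages are available: rigid (6 parameters,
finite-difference gradients in scaled units of degrees/mm), affine (12
parameters) and a cubic B-spline free-form deformation composed as
\(y = L(x + u(x))\) with analytic chain-rule gradients scattered onto the
control points (default spacing 40 mm). Desk-scale defaults are 150
iterations per level, 1024 samples, pyramid 4/2/1; `full_scale = TRUE`
selects 2000 iterations, 2048 samples and pyramid 8/4/2/1 for
full-resolution volumes. Samples falling outside the moving volume read
as zero, which is appropriate for air-backed anatomy.

Known-transform recovery on phantoms (±4 mm shifts, ±5° rotations) is
accurate to well under 0.5 mm / 0.5°, and is exercised in the test suite
across seeds.

## The 3D U-Net engine

`seg_unet` is a configurable encoder-decoder with skip connections,
implemented natively (single-precision im2col + BLAS convolutions with
persistent workspace buffers, so whole-volume training fits a single CPU).
Architecture family: per encoder level two 3³ convolution blocks
(convolution → affine-free instance normalisation → leaky ReLU, slope
0.01) and a 2³ max-pool; two bottleneck blocks; per decoder level
nearest-neighbour upsampling, one block, concatenation of the skip
features and two further blocks; a final 1x1x1 projection to one sigmoid
channel per label code plus background. Instance norm and leaky
activations are the standard conditioning for whole-volume 3D
segmentation training: without them, batch-of-one gradient steps either
diverge or strand units in a dead constant-background solution.

The loss is per-channel binary cross-entropy against the one-hot target
stack, with deep supervision: each coarser decoder level carries an
auxiliary 1x1x1 head scored by the same BCE against stride-downsampled
targets, with weights halving per level (normalised to sum 1). The coarse
heads see far better foreground/background balance, which pulls the shared
trunk toward the anatomy early; inference uses only the full-resolution
output. The optimiser is Adam at the configured learning rate with a
30-step linear warm-up (early second-moment estimates are uninformative
and whole-volume batches make the first steps violent without it). The
final layers' biases are initialised to +2 for background and −2 for
foreground channels — a prior-informed initialisation reflecting that
muscle voxels are a few percent of the volume, so optimisation starts at
the "all background" operating point instead of spending its budget
finding it. Early stopping monitors validation loss and restores the
weights of the arg-min epoch.

Inference reduces the nine sigmoid channels to a single label map by
argmax with ties resolved toward the background channel (the hot-encoded
output plus BCE does not itself fix an inference rule; argmax including an
explicit background channel is the natural reduction).

Two configurations are documented:

* `unet_config()` — the full-scale family (4 levels, 16 base filters,
  learning rate 1e-4, batch size 1, whole-volume inputs). With kernel 3
  and growth 2 this recipe counts 5.3 M parameters; smaller growth or a
  single conv per block lands in the low millions if a leaner budget is
  wanted — the count is reported exactly by `build_unet()` and tested
  against a hand-computed closed form.
* `desk_unet_config()` — 3 levels, 8 base filters, learning rate 0.05 and
  30 epochs, sized for the 64 x 64 x 32 phantom cohort used by the tests
  and the acceptance script. The large step size is deliberate: desk
  schedules take a few hundred optimisation steps, and Adam moves each
  parameter by roughly the learning rate per step. The early-stopping
  abort is disabled (patience 0) because short schedules show transient
  validation spikes while the last structures are still being learned;
  the arg-min validation epoch is still the one restored.

Leakage is guarded twice: `train_unet()` refuses train/validation sets
sharing subject ids, and `mc_cross_validate()` applies augmentation only
inside each fold's training subset, asserting the plan's leakage freedom
structurally.

## Multi-atlas baseline

`segment_multiatlas()` registers every atlas (affine, then B-spline) to
the target, ranks the warped atlases by descending NCC against the target
in-phase image (ties by library order; ranking uses the registered
atlases), propagates the labels of the top k = 5 through the composed
transform with nearest-neighbour interpolation, and fuses them by strict
majority voting: a code wins a voxel only if more than k/2 maps agree;
competing codes resolve by vote count, ties toward the lowest code. When
the target id is in the library it is excluded (leave-one-out).
Post-processing applies a soft-tissue mask — labelled voxels whose FF
exceeds 0.80 are removed, stripping subcutaneous fat dragged in by
registration error (the threshold is configurable; real data may prefer an
automatic threshold) — followed by per-code 3D hole filling
(border-connected background flood fill; filling claims only background
voxels).

## Fat-fraction measurement

`ff_map()` computes FF = F/(W+F) where W+F exceeds
\(\varepsilon = 10^{-6} \max(W+F)\); air voxels are flagged invalid, never
silently zero. `mean_ff()` averages the valid voxels of one label code
(reported in percent), optionally restricted to an inclusive 1-based
axial slice range — the crop compensating for scans whose inferior
coverage truncates psoas/iliacus. `bilateral_mean()` averages the left
and right side means *unweighted* (one value per muscle per subject, the
convention behind normative tables); a voxel-weighted variant exists
behind a flag, and a test pins down that the unweighted value is the one
returned.

## Evaluation and statistics

* **Dice** 2|A∩B|/(|A|+|B|); two empty masks score 1.0 (perfect agreement
  on absence — the convention is logged here because the degenerate case
  never arises in practice but must be defined).
* **RVD** (V_pred − V_truth)/V_truth x 100, signed, prediction minus truth.
* **Hausdorff** max of the two directed max-min Euclidean distances
  between boundary voxel centres (6-connectivity), in mm via the voxel
  spacing; the maximum (not 95th percentile) is the default. Both Dice and
  Hausdorff are verified against brute-force oracles on random masks.
* **Monte-Carlo CV planning** (`mc_cv_plan()`): n_folds random validation
  draws of n_val subjects without within-fold replacement, resampled
  (bounded retries) until every subject appears in at least one validation
  set; repeats across folds are allowed. The default 26/5/8 layout yields
  18 training subjects per fold and 40 pooled validation entries.
* **Bland-Altman** (`bland_altman()`): bias = mean(y−x), limits of
  agreement ± 1.96 sample SD, plus a linear regression of y on x with R².
* **Kruskal-Wallis** via `stats::kruskal.test` (used even for two groups).
* **Type III ANCOVA** (`ancova_type3()`): sum-to-zero contrasts for
  categorical effects; each effect's SS is the residual-SS increase when
  its columns are removed with all others retained; partial
  η² = SS_eff/(SS_eff+SS_res), algebraically df1·F/(df1·F+df2) — the
  identity `partial_eta_sq()` exposes directly so published (F, df) pairs
  can be converted. Rank-deficient designs error naming the aliased terms.
  `car::Anova` serves as an independent oracle in the tests, never as the
  implementation.
* **Reference tables** (`reference_table()`): median and 25th/75th
  percentiles (type-7 linear interpolation) of bilateral-mean FF per
  muscle, optionally stratified by activity group or sex; empty cells are
  flagged, not fabricated.

## Numerical and design choices

* Axes are (x, y, z) = (left-right, anterior-posterior, slice); voxel
  indices are 1-based and crop ranges inclusive — R convention, stated
  here because no axis convention is universal.
* Label codes are fixed 1–8, left before right (P, I, QL, ESM); flips
  swap the pairs.
* NIfTI-1 carries geometry in an axis-aligned sform with positive
  diagonal; geometry survives round-trips to well under 1e-6 mm. Label
  code tables travel as JSON sidecars.
* Registration determinism: a seed fixes the voxel sampler; all module
  seeds fan out from one pipeline seed via fixed per-stage offsets so any
  stage can be reproduced in isolation.
* The problem sizes used by the automated checks — 24-phantom cohorts
  (16 train / 8 val) with the full linear augmentation of the training
  subset (`linear_augment()`: flips with label swap plus 0°/±5°/±10°
  rotations, 160 training images per epoch, 6 epochs; the rotational
  diversity is what makes every compartment converge reliably inside the
  short schedule), a 10-atlas library (a subset of the labelled training
  subjects, as in the full-scale baseline design) for the shared
  multi-atlas benchmark plus a 10-phantom leave-one-out, and 200-subject
  statistical cohorts — were chosen so the full suite runs on one desktop
  CPU core; the same code paths scale to full-resolution data by
  switching configurations.

## Known limitations

* The phantom's piecewise-constant tissues omit partial-volume mixing,
  Rician noise, bias fields and chemical-shift artifacts; phantom
  performance bounds real performance from above.
* The U-Net engine is single-threaded CPU code; full-resolution
  (400 x 320 x 145) whole-volume training is supported by the
  architecture but needs several GB of workspace memory and long
  schedules — a GPU framework is the right tool at that scale.
* Deformable transforms are not invertible in closed form; label
  propagation always composes forward transforms instead.
* The ANCOVA is a fixed-effects linear model; repeated measures or site
  effects would need mixed models, which are out of scope.
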