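---
title: "Decoding block-design brain states: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding block-design brain states: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the science implemented by `brainstate`: the decoding
model, the preprocessing conventions, the permutation test, what the
synthetic generator does and does not emulate, and the design decisions
taken where the method leaves room.

## The decoding model

The paradigm is a strictly alternating task/rest block schedule
(`paradigm()`): by default five cycles of 30-s blocks, 300 s in total, task
first. Blocks are half-open intervals `[start, end)`, so a frame acquired
exactly on a boundary belongs to the later block — an arbitrary but
order-independent convention. A frame's time is its acquisition start,
`i * TR` with 0-based `i`.

Each acquired volume is one example; its label is the paradigm state at its
frame time. The classifier is the linear soft-margin SVM in its trade-off
form

$$\min_{w,b}\; \lVert w\rVert^2 + C\sum_i \xi_i
\quad\text{s.t.}\quad y_i(w^\top x_i + b)\ \ge\ 1-\xi_i,\ \ \xi_i \ge 0,$$

with $C = 1$ by default. Note the objective carries no factor $\tfrac12$ on
the quadratic term: solvers written for
$\tfrac12\lVert w\rVert^2 + C'\sum\xi_i$ are equivalent under $C' = C/2$,
and `train_svm()` applies exactly that mapping to its libsvm backend
(`e1071`), so the `C` you pass always refers to the objective above. This
equivalence, and the solution itself, are verified in the test suite against
`svm_solve_exact()`, an independent exact solver that enumerates the
$3^n$ active-set patterns of the dual on small instances.

Two further conventions: a bias term $b$ is included by default (libsvm
fits one; the decision function is often written without it, and
`bias = FALSE` forces the plane through the origin via an internal dual
coordinate-descent solver); and a decision value of exactly zero predicts
$+1$. Class orientation does not depend on example order: the $+1$ examples
are presented to the backend first, which pins libsvm's internal class
ordering.

Performance is *cross-run* accuracy: train on run 1, test on run 2, and
vice versa; `accuracy_curve()` averages the two directions within subject
before averaging subjects (the aggregation order is otherwise
inconsequential for balanced designs, but both per-direction rows and the
aggregate are kept in the result).

## Preprocessing conventions

- **Brain mask** (`brain_mask()`): computed from the unsmoothed mean image —
  for control/tag contrasts, the mean of the *control* frames (the baseline
  image). The default rule keeps voxels at or above the global mean
  intensity, which on a bright-brain/dark-background image keeps the brain
  and reduces the feature count from the full 45,056-voxel grid to the
  in-brain subset. The literal "within one SD of the mean" band rule is
  implemented (`rule = "band"`) but not the default: on such images it
  keeps the background and discards the brightest brain voxels, as one of
  the unit tests documents on a toy volume. A softer
  `"above_mean_minus_sd"` threshold is also available.
- **Surround subtraction** (`surround_subtract()`): with signs $s_i = +1$
  for control and $-1$ for tag frames,
  $out_0 = s_0(x_0 - x_1)$ and
  $out_i = s_i\,(x_i - (x_{i-1}+x_{i+1})/2)$ for interior $i$, giving
  $N-1$ outputs. This form was chosen because it annihilates any signal
  affine in time at interior frames (drift robustness), recovers a constant
  control-minus-tag offset exactly at every output frame, and yields the
  expected example count (75 raw ASL frames at TR 4 → 74 examples per
  300-s run). Output frames keep the leading raw frame times.
- **Smoothing** (`smooth_gaussian()`): separable 3D Gaussian,
  $\sigma_\text{axis} = \mathrm{FWHM} / (2\sqrt{2\ln 2}) / \text{voxel
  size}$, kernel truncated at $4\sigma$ and renormalized at volume edges,
  so constants are preserved exactly and interior mass is conserved.
- **Normalization** (`normalize_voxelwise()`): per-voxel temporal
  z-scoring with the sample (N−1) SD; zero-variance voxels become zero.
  Normalization is computed per run — training and testing runs never share
  statistics, so no information leaks across the train/test split.
- **Order**: control/tag runs are subtracted first, then smoothed, then
  normalized; BOLD runs are smoothed then normalized. The mask always comes
  from unsmoothed data.
- **Subsampling** (`subsample_run()`): keeping every `stride`-th frame
  multiplies the effective TR accordingly (TR-2 BOLD → 75 examples at
  effective TR 4 s), used to equalize example counts across contrasts.

SD computations use the N−1 denominator throughout, which makes the
`[1, 2, 3] → [−1, 0, 1]` normalization example exact.

## Transition exclusion

A paradigm with $2n$ blocks has $2n - 1$ state transitions (nine in the
default design). Frames acquired near a transition are ambiguous: the
vascular response is still ramping toward the new state while the label has
already switched. `excluded_frame_indices()` drops, per transition, the last
`k` frames of the preceding block and the first `k` of the following block,
identically for training and testing sets; exclusion is monotone in `k` and
for subtracted series operates on the subtracted frames through their frame
times (operating on raw frames instead is a configuration choice, since
"one time point" is ambiguous between the two series).

## The permutation test

The weight vector of a linear SVM, folded back into brain space, localizes
the discriminative voxels. To attach voxel-wise significance,
`permutation_null()` retrains the SVM on `n_perm` random rearrangements of
the labels; after normalizing every weight vector to unit sample SD, each
voxel's p-value is the fraction of permutations whose statistic meets or
exceeds the original — with 2,000 permutations at the 1% level, exactly the
rule "exceedance count below 20". Only running counts are kept, so memory
does not grow with `n_perm`.

Two statistics ship because the method's two natural readings differ: a
voxel's discriminative importance is the *magnitude* of its weight
(`"absolute"`, the default, a two-sided test), while the literal one-sided
count compares signed weights (`"signed"`). Both are calibrated on
label-independent data in the acceptance suite. p-values are
`count / n_perm` exactly; an optional `(count+1)/(n_perm+1)` estimator
avoids zero p-values. Labels are permuted freely by default; with
temporally autocorrelated data free permutation is mildly anticonservative
(the acceptance suite measures a false-positive fraction of roughly
1–1.5× the nominal level under AR(1) noise), and a block-permutation option
(permuting whole 30-s blocks) is provided for that case.

**Design choice — which examples feed the weight map.** The experiment
driver estimates weight maps from the transition-excluded example set
(`perm_k = 3` by default). Transition frames carry the previous state's
signal and act as label noise; on synthetic subjects they de-localize the
weight map badly (mean Dice against the ground-truth region 0.33 with all
frames vs 0.97 with exclusion, at 10 subjects). Offline analyses that omit
transition periods are standard practice for block designs, and accuracy is
reported across the full sweep `k = 0…3` regardless.

## The synthetic generator

`generate_run()` emulates what the analysis needs and nothing more:

- **Geometry**: a 64×64×11 grid at 3.75×3.75×6 mm by default (24-cm FOV);
  an ellipsoidal "brain" and two activated ellipsoids ("motor" and
  "visual") defined in fractional coordinates, so the same geometry scales
  to reduced grids.
- **Signal**: the task boxcar convolved with a double-gamma hemodynamic
  response (positive lobe peaking at 6 s, undershoot at 16 s, ratio 1/6,
  unit peak; `hrf_double_gamma()` parameterizes the lobes by their modes).
  The regressor is rescaled to unit maximum so that CNR — activation
  amplitude over noise SD — reads directly in noise-SD units.
- **Modalities**: BOLD carries the activation on every frame plus a linear
  drift (0.03 a.u./s by default, BOLD only: subtraction contrasts cancel
  drift by construction). Control/tag runs carry the baseline
  control-minus-tag offset (15 a.u.) and the activation on control frames
  only, control first. AVAST TR is drawn per subject from the tailored-TR
  table (2.0–2.5 s with frequencies 2, 2, 2, 3, 1 of 10); ASL uses TR 4 s,
  BOLD TR 2 s. Dummy scans are not simulated; the run covers the paradigm
  exactly, `floor(300 / TR)` frames.
- **Noise**: voxel-wise AR(1) with coefficient 0.3 and innovation SD 10
  a.u., everywhere (outside the brain: noise only). The AR structure is
  there so that drift robustness and transition exclusion have something
  realistic to push against.
- **Determinism**: a run is a pure function of (parameters, seed); the two
  runs of a subject share every deterministic component and differ only in
  their noise streams. Subject seeds derive from the master seed by one
  seeded draw, so any subject is independently reproducible.

**CNR defaults** are `c(bold = 2, asl = 1.2, avast = 4)`. These are
configuration, not physiological claims: no quantitative SNR is available
for the three contrasts, so the defaults were calibrated once — on the
reduced 16×16×4 study grid with 10 subjects — to reproduce the qualitative
regime of interest: AVAST above perfusion ASL at every exclusion level,
end-to-end accuracies in (0.7, 1.0) rather than saturated, ASL benefiting
from one-frame exclusion but deteriorating at three (its 12-s-per-side
exclusion starves the 74-example runs), and AVAST above 0.9 in the
transition-excluded analysis. Only such orderings and trends are
meaningful on synthetic data; absolute accuracies are not comparable to any
real acquisition.

What the generator does **not** emulate: MR physics (tag relaxation, Bloch
dynamics, off-resonance), motion, susceptibility artifacts, physiological
noise spectra, spatial noise correlation, and between-subject anatomical
variability. Passing tests therefore demonstrate correctness of the
analysis machinery and sane statistical behavior under a known model — not
performance on real scanner data.

## Numerical choices

- SVM solver tolerance defaults to `1e-8`; the small-instance enumeration
  oracle agrees with the backend to better than `1e-6` in objective value
  over randomized instances (and exactly satisfies the KKT conditions by
  construction).
- Tie-break: decision value 0 → class +1. Zero-variance voxels normalize
  to zero. An all-zero weight vector is left unchanged by unit-SD
  normalization.
- Degenerate exclusion (`k` larger than a block's frame count) empties the
  block with a warning; emptying the whole run is an error.
- Problem sizes in the acceptance suite: the synthetic study runs 10
  subjects on a 16×16×4 grid (the full-FOV geometry at coarse resolution)
  with 200 permutations per weight map; the SVM oracle sweep uses 100
  random instances of up to 6 examples and 3 features; the permutation
  calibration uses 50 replicates of 40 examples × 20 voxels. These sizes
  keep the whole verification run in the minutes range on a single core
  while leaving every statistical check well-powered.

## Known limitations

- The permutation null retrains the SVM per permutation; with thousands of
  permutations on full-resolution data this is the dominant cost (the
  counts-only memory contract keeps space constant, but time is linear in
  `n_perm`).
- Free label permutation ignores temporal autocorrelation; use
  `block_permute = TRUE` when that matters.
- The experiment driver evaluates the two train/test directions per
  subject and averages; per-direction rows are retained, but no
  variance decomposition across direction vs subject is attempted.
- The generator's activation amplitude is spatially uniform inside each
  ellipsoid; there is no partial-volume gradient at region borders, which
  makes localization Dice more forgiving than on real data.
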