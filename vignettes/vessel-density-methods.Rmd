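---
title: "Methods: parafoveal vs. perifoveal vessel density for glaucoma discrimination"
author: "octavd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parafoveal vs. perifoveal vessel density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the pipeline

Glaucomatous damage to retinal ganglion cells is accompanied by capillary
loss that is visible in en-face OCTA projections of the macula. Clinical
OCTA analysis of 3x3 mm scans conventionally quantifies vessel density (VD)
in a parafoveal annulus around the fovea and discards the remaining corners
of the scan. `octavd` implements a complete, testable pipeline for asking
whether those discarded perifoveal corners are in fact the more informative
region:

1. **Enhance** — multiscale Frangi vesselness filtering of each en-face
   plexus projection (SVP, ICP, DCP).
2. **Binarize** — a single global Otsu threshold on the vesselness map.
3. **Regions** — VD (percent vessel pixels) in 12 parafoveal sectors
   (an annulus of 2.9 mm outer diameter, FAZ excluded) and 4 perifoveal
   corner quadrants.
4. **Experiment** — for each of the six methods (3 plexuses x 2 zones), a
   support vector machine is selected by patient-grouped 10-fold
   cross-validation on AUROC and evaluated on a held-out test set.
5. **Stats** — one-way ANOVA over the six groups of per-fold AUROCs with
   Bonferroni-corrected post-hoc pairwise comparisons.

Because clinical registry data cannot be shipped, the package includes a
synthetic angiogram generator with *known* class structure; every stage of
the pipeline is validated against it and against exact numeric oracles.

## Vesselness enhancement

For a Gaussian scale $\sigma$, the scale-normalized Hessian eigenvalues
$|\lambda_1| \le |\lambda_2|$ give the blobness ratio
$R_B = \lambda_1/\lambda_2$ and structureness
$S = \sqrt{\lambda_1^2 + \lambda_2^2}$. For bright-on-dark vessels the
response is 0 where $\lambda_2 \ge 0$, otherwise

$$ v_\sigma = \exp\!\left(-\frac{R_B^2}{2\beta^2}\right)
   \left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right), $$

and the final map is the pixelwise maximum over scales.

Parameter choices (all exposed in `vesselness_params()`):

* `scales_px = c(1, 1.5, 2, 3)` — capillaries at 5.7 um/px are 1-3 px wide;
  the coarsest scale covers superficial arterioles.
* `beta = 0.5` — the canonical blobness sensitivity.
* `c = "auto"` — half the maximum Hessian Frobenius norm per scale, a
  standard self-scaling choice; a fixed positive value is accepted.

Numerical choices worth knowing:

* Gaussian-derivative kernels are truncated at $4\sigma$; the
  second-derivative kernel is mean-corrected so a constant image yields an
  exactly zero Hessian despite truncation.
* Boundary handling is symmetric reflection. Zero padding would create a
  bright-edge ridge artifact precisely in the perifoveal corners being
  measured, biasing the comparison the package exists to make.
* A structureness floor ($S > 10^{-10}$) keeps float-level curvature from
  producing spurious vesselness on flat images.
* Eigenvalue ties $|\lambda_1| = |\lambda_2|$ need no tie-break: the
  formula is symmetric in that case.

## Binarization

Otsu's threshold maximizes the between-class variance
$\omega_0\omega_1(\mu_0-\mu_1)^2$ over a 256-bin histogram. Three fixed
conventions make results bit-reproducible:

* the histogram spans the data range (making the threshold exactly
  equivariant under affine intensity rescaling),
* ties break toward the smallest threshold,
* the vessel class is *strictly above* the returned bin edge.

The threshold is global (one per image), matching a chain in which a single
binarization precedes regional VD; no morphological cleanup is applied. A
constant (single-class) map is an error rather than a silent all-background
result, and that error propagates out of `extract_features()`.

## Region layout

Membership is decided at pixel centers with half-open radial boundaries
(`inner < r <= outer` parafoveal, `r > outer` perifoveal), so the 12 sectors,
4 quadrants and the FAZ disk tile the image exactly once — a property tested
across geometries. Conventions, all configurable:

* **FAZ exclusion**: 0.5 mm radius by default (the ETDRS central-subfield
  radius); the source chain states the exclusion but not a radius.
* **Sectors**: S1 starts at 12 o'clock and sectors advance clockwise. The
  choice is arbitrary; the downstream SVM is insensitive to any consistent
  relabeling.
* **Quadrants**: axis-aligned split through the fovea center, matching the
  "four corners of the image" reading; Q1 = top-right, counter-clockwise
  naming Q2, Q3, Q4 by corner.
* Left eyes are *not* mirrored to anatomical (nasal/temporal)
  correspondence; nothing in the source chain requires it and the
  classifiers are permutation-insensitive, but anatomically-resolved sector
  interpretation would need it.

`vessel_density()` is the exact ratio `100 * vessel / total` within a mask;
a zone VD is the mask-size-weighted mean of its regions (a conserved
quantity used as a test invariant).

## The experiment protocol

The source protocol states both a 60/20/20 train/validation/test split and a
10-fold cross-validation. These are reconciled in the most common reading:
20% of eyes are held out as the test set by whole patients, stratified by
class; the remaining 80% is partitioned into 10 patient-grouped folds, so
each fold trains on about 60% of all eyes and validates on about 20%. Every
configuration in the hyperparameter grid is scored by mean validation-fold
AUROC; the winner (ties to the earliest grid entry) is refit on all non-test
data and evaluated once on the test set. All six methods share the same
split and the same folds, making per-fold AUROCs comparable across methods.
The per-fold metrics reported for each method are those of its winning
configuration on the validation folds; this reading is recorded in the run
manifest.

Further decisions:

* **No leakage, structurally**: patients are atomic in the split and in the
  folds, and `run_full_experiment()` asserts this on every run.
* **Decision threshold**: sensitivity/specificity/F1 use the SVM's native
  boundary `f(x) > 0` — parameter-free, since no operating point is stated.
* **Standardization**: features are z-scored with training-fold statistics
  only (polynomial/sigmoid kernels are scale-sensitive; this is the
  leakage-safe variant).
* **Grid**: `default_svm_grid()` spans all four kernels
  (linear, polynomial degrees 2-4, RBF, sigmoid) with C in
  $10^{-2}..10^3$ and the `1/(p\,\mathrm{var}(x))` kernel-coefficient
  heuristic — 36 configurations. `compact_svm_grid()` (12 configurations,
  all four kernels) is used in tests where runtime matters; effect-recovery
  conclusions do not depend on grid size.
* **Class imbalance** (the emulated cohort is ~56% glaucoma): no reweighting
  by default, mirroring the source protocol's silence; `svm_fit()` exposes
  `class_weights`.

The SVM itself is solved in-package by a deterministic SMO dual solver
(C++), since no SVM library is available in the target environment; all
randomized scan orders in classic SMO are replaced by fixed orders so
training is bit-reproducible.

## Statistics

The six methods' per-fold AUROCs (k = 10 each, N = 60) enter a one-way
ANOVA; post-hoc pairwise comparisons use the pooled-error t statistic

$$ t = \frac{m_i - m_j}{\sqrt{MS_\text{within}(1/n_i + 1/n_j)}} $$

on $N-k$ degrees of freedom, with two-sided p-values multiplied by the
number of pairs (15) and capped at 1 — the SPSS "Bonferroni" post-hoc
convention, chosen because that procedure is named by the source protocol.

**Caveat, by design**: fold AUROCs computed on a shared fold partition are
not independent observations; treating them as such (as the source protocol
implicitly does) inflates significance. The package reproduces the
procedure and documents the caveat rather than correcting it;
correlated-fold corrections (e.g. Nadeau-Bengio) and DeLong tests on pooled
predictions are deliberate non-goals of the default path.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` produces a deterministic, seeded cohort emulating the
registry that motivated the pipeline: ~352 eyes of 240 patients (~47%
contributing both eyes, all eyes of a patient sharing one label, ~56%
glaucoma), 3x3 mm fovea-centered angiograms per plexus with a central
avascular zone, and demographic metadata with class-specific age/sex mixes.

Vessels are stochastic random-walk segments: a capillary mesh for every
plexus (short curved walks, ~0.45 mm mean length), plus 6-10 thick
border-seeded arterioles with branches for the SVP, steered tangentially
around the fovea. Centerlines are rasterized and blurred to physical width;
widths are floored at rasterization (capillaries 0.6 px, arterioles 1.3 px)
so sub-pixel vessels at reduced test resolutions still render as clean
ridges while the thick/thin distinction survives at every resolution.
Multiplicative speckle (`intensity * (1 + noise * N(0,1))`, clipped to
[0, 1], default amplitude 0.15) approximates OCTA granularity.

Disease is *region-weighted segment dropout*: each zone-homogeneous piece of
a path survives with probability `1 - dropout_zone * plexus_scale`. Segments
are split at the parafoveal boundary before the draw, so dropout in one zone
never removes pixels from the other — the basis of the effect-locality
property test. Arterioles drop at half the capillary rate (structural
vessels are more resilient than capillaries).

Default disease parameters are chosen once to mirror the qualitative
structure of the motivating finding, not tuned to any metric: perifoveal
dropout 0.35 vs. parafoveal 0.15 (perifovea-dominant), plexus scaling
SVP 1.0 > ICP 0.7 > DCP 0.45, and a 15% lognormal coefficient of variation
on per-eye capillary density — a realistic inter-individual VD spread that
keeps classes overlapping, so AUROCs are informative rather than saturated.
Capillary densities (26-33 paths/mm^2 by plexus) put the binarized vessel
fraction near the middle of the 20-60% plausibility band.

What the generator does **not** model: OCTA decorrelation/speckle physics,
projection artifacts between plexuses, axial structure, segmentation errors,
media opacity, real FAZ shape variation (the FAZ is a disk of configurable
radius, default 0.25 mm), or vascular anatomy beyond "curvilinear bright
structures at two width classes". A green designed-effect test therefore
establishes that the *pipeline* recovers a known region-weighted effect from
images with realistic nuisance structure — it does not certify clinical
performance on real angiograms.

## Degenerate inputs and edge policies

* Constant images fail binarization loudly (`degenerate`), and the error
  propagates through feature extraction.
* Folds whose validation part contains one class abort with a clear
  "cohort too small or imbalanced" message rather than returning NaN AUROC.
* Zero within-group variance with unequal means yields `F = Inf, p = 0`;
  fully identical values are an error.
* Constant features are left unscaled (sd treated as 1) during
  standardization.
* Random generation consumes survival uniforms even when dropout is zero, so
  a healthy and a diseased render from the same seed differ *only* in
  dropped segments — the basis of paired-construction tests.

## Known limitations

* The Frangi parameters of the original MATLAB analysis tool are not public;
  parity with it is not claimed, only faithfulness to the published chain
  (Frangi -> Otsu -> regional ratio).
* VD depends on the binarization operating point; absolute synthetic VD
  percentages are not comparable to clinical normative values.
* At the default test resolution (96-128 px) capillaries are near the
  rasterization floor; absolute vesselness contrast between plexuses is
  weaker than at the native 526 px geometry (the thick-vessel coarse-scale
  contrast is preserved and tested).
* The statistics module inherits the fold-independence caveat above.
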