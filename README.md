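# octavd — macular vessel density in en-face OCTA, parafovea vs. perifovea

`octavd` is an R package for a question in glaucoma imaging: in a 3×3 mm
macular OCTA scan, is the **perifoveal** vessel density (the scan's four
corner quadrants, conventionally discarded) a better glaucoma discriminator
than the **parafoveal** vessel density (the standard annulus around the
fovea)? It is aimed at ophthalmic-imaging researchers who want the full
analysis chain — from en-face angiogram to Bonferroni-corrected method
comparison — as tested, reproducible code rather than a one-off script.

## What it computes

For each eye and each retinal plexus (SVP, ICP, DCP), an en-face projection
is processed as:

1. **Frangi vesselness** `v = max_σ exp(−R_B²/2β²)(1 − exp(−S²/2c²))`, with
   `R_B = λ₁/λ₂`, `S = √(λ₁²+λ₂²)` from the σ²-normalized Hessian
   eigenvalues (`|λ₁| ≤ |λ₂|`, bright-on-dark polarity: zero where λ₂ ≥ 0).
2. **Otsu binarization** of the vesselness map (global 256-bin threshold
   maximizing between-class variance).
3. **Regional VD** `= 100 · vessel px / region px` in 12 parafoveal sectors
   S1…S12 (annulus 0.5–1.45 mm, FAZ excluded) and 4 perifoveal corner
   quadrants Q1…Q4.
4. **SVM evaluation** per method (plexus × zone): a patient-grouped 60/20/20
   split with 10 patient-grouped folds, hyperparameter selection by mean
   validation AUROC over a grid of linear/polynomial/RBF/sigmoid kernels,
   held-out test evaluation, and per-fold AUROC / sensitivity / specificity /
   F1.
5. **Statistics**: one-way ANOVA across the six methods' per-fold AUROCs and
   pooled-error t pairwise comparisons with Bonferroni correction.

No clinical data ships with the package. A synthetic cohort generator
(`generate_cohort()`) produces seeded angiogram cohorts with known,
region-weighted vessel dropout so the entire chain is testable; see the
methods vignette (`vignettes/vessel-density-methods.Rmd`) for what it does
and does not emulate.

## Worked example

A 120-eye synthetic cohort at reduced resolution (128 px, 3 mm field) with
the default disease model — perifovea-dominant dropout, strongest in the
SVP:

```r
library(octavd)

cfg <- synth_config(image_size_px = 128, pixel_size_mm = 3/128,
                    n_patients = 100, two_eye_fraction = 0.2, seed = 11)
cohort <- generate_cohort(cfg)
print(cohort)
#> <octa_cohort> 120 eyes of 100 patients (64 glaucoma / 56 healthy eyes)

experiment <- run_full_experiment(cohort, grid = compact_svm_grid(), seed = 3)
print(experiment)
#> <vd_experiment>
#>   SVP.parafoveal   AUROC 0.598 +/- 0.227  [svm(kernel=polynomial, C=10, degree=2, gamma=scale, coef0=1)]
#>   ICP.parafoveal   AUROC 0.663 +/- 0.195  [svm(kernel=rbf, C=0.1, gamma=scale, coef0=0)]
#>   DCP.parafoveal   AUROC 0.667 +/- 0.186  [svm(kernel=linear, C=0.1)]
#>   SVP.perifoveal   AUROC 0.922 +/- 0.093  [svm(kernel=linear, C=0.1)]
#>   ICP.perifoveal   AUROC 0.827 +/- 0.122  [svm(kernel=rbf, C=0.1, gamma=scale, coef0=0)]
#>   DCP.perifoveal   AUROC 0.808 +/- 0.093  [svm(kernel=rbf, C=0.1, gamma=scale, coef0=0)]
#>   ANOVA: F = 5.855, p = 0.0002163
```

Each line is one method's 10-fold mean ± SD AUROC and the hyperparameter
configuration the validation folds selected. In this seeded cohort the
perifoveal features beat the parafoveal ones for every plexus, most strongly
for the SVP (0.922 vs. 0.598) — the designed effect, recovered by the
pipeline. The ANOVA says the six methods differ; the Bonferroni table shows
which pairs drive it:

```r
print(experiment$pairwise)
#>                SVP.parafoveal ICP.parafoveal DCP.parafoveal SVP.perifoveal ICP.perifoveal DCP.perifoveal
#> SVP.parafoveal                         1.000          1.000        <0.001*         0.039*          0.079
#> ICP.parafoveal                                        1.000         0.011*          0.405          0.728
#> DCP.parafoveal                                                     0.013*          0.465          0.826
#> SVP.perifoveal                                                                     1.000          1.000
#> ICP.perifoveal                                                                                    1.000
#> DCP.perifoveal                                                                                         
#> * adjusted p < 0.05 (Bonferroni over 15 pairs)

experiment$results$SVP.perifoveal$test["auroc"]
#> 0.902  (held-out patient-grouped test set)
```

Cells are Bonferroni-adjusted p-values of pooled-error t comparisons of
per-fold AUROCs; starred cells are significant at α = 0.05. Visual QC of the
region layout over an angiogram:

```r
lay <- make_region_layout(cohort[[1]]$images$SVP)
plot_region_overlay(cohort[[1]]$images$SVP, lay)
```

## Command-line use

```sh
Rscript inst/scripts/synth-cohort.R  --out cohort/  --seed 1 [--config cfg.yaml]
Rscript inst/scripts/run-experiment.R --cohort cohort/ --out results/ --seed 1 \
        --pixel-size-mm 0.0057 --k 10 --grid default
```

`synth-cohort.R` writes one grayscale PNG per eye per plexus plus
`cohort.csv`; `run-experiment.R` writes per-region VD, the metrics table,
the pairwise table and a JSON run manifest (all deterministic for a fixed
seed).

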