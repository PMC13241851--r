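# brainergetics

Regional brain energetics pattern analysis from simultaneous FDG-PET /
ASL-MRI data, for neuroimaging researchers studying how the spatial
organization of brain energy metabolism changes with healthy aging and how
those changes relate to neurodegenerative metabolic patterns.

## What it computes

Two orthogonal, per-subject regional metrics are derived from z-scored
CMRglu (glucose metabolism) and CBF (blood flow, a spatial proxy for
CMRO₂ under uniform oxygen extraction):

```
rEP = (z(CBF) + z(CMRglu)) / √2     relative energy production (concurrence)
rAG = (z(CMRglu) − z(CBF)) / √2     relative aerobic glycolysis (discordance)
```

On top of these the package provides:

* **SSM-PCA age patterns** — double-demeaned residual profiles, PCA,
  component filtering (VAF > 5%, group-separation t-test p < 0.2),
  AIC-stepwise logistic recombination, and 500 × 5-fold cross-validation
  yielding a spatial covariance pattern whose expression separates
  younger (≤ 60 y) from older (> 60 y) subjects, with per-region
  stability SDs, separation statistics (t, p, Cohen's d) and a score–age
  fit (r², p).
* **PLSC** — SVD of the clinical-by-region correlation matrix (age, sex)
  with permutation significance and bootstrap salience stability, used to
  validate the SSM-PCA topographies.
* **TPR scoring** — regionalized Topographic Profile Rating
  (`rSRP = log rCMRglu − rGMR − rGMP` projected onto disease-pattern
  weights) with Spearman/Pearson pattern comparisons and Bonferroni
  adjustment over the comparison family.
* **Kinetic quantification** — Patlak graphical estimation of the FDG net
  uptake rate Ki, CMRglu = Ki·Cglu/LC (LC = 0.65), a simplified
  image-derived input function, ROI aggregation of parametric volumes, and
  an exact 1-D k-means subdivision of the putamen along the
  anterior–posterior axis.
* **A synthetic cohort generator** — log-additive cohorts (24 subjects,
  97 regions, ages 35–80 by default) with a planted unit-norm spatial
  pattern whose expression varies linearly with age, entering both
  modalities concordantly (an rEP effect) or discordantly (an rAG
  effect), so every stage is testable without subject data.

## Worked example

```r
library(brainergetics)

ds  <- generate_regional_cohort(cohort_config(pattern_mode = "concordant", seed = 7))
tab <- build_energetics_table(ds)
pat <- crossvalidate_pattern(tab$rep, ds$ages, n_iter = 500, seed = 1, metric = "rep")
pat
#> covariance_pattern (rep): 97 regions, 2500 CV patterns retained
#>   separation: t = 8.00, p = 5.9e-08, Cohen's d = 3.47
#>   age fit: r2 = 0.956, p = 2.2e-16
abs(cosine_similarity(pat$weights, ds$planted_pattern))
#> [1] 0.970
```

The planted concordant pattern (an age-linked restructuring of energy
production) is recovered with cosine 0.97 despite log-scale noise of
SD 0.3; its expression separates the age groups (d = 3.47) and tracks age
(r² = 0.96). Note the separation and age-fit statistics are in-sample and
selection-inflated — treat them as descriptive and use the PLSC
permutation p for calibrated inference (see the methods vignette,
`vignettes/brain-energetics-methods.Rmd`).

The full pipeline — simulate → energetics → rEP/rAG patterns → PLSC →
disease-pattern comparison, with a deterministic manifest — runs as:

```r
run_pipeline(pipeline_config(seed = 1), "runs/demo")
```

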