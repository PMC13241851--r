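---
title: "Methods: regional brain energetics and age-related covariance patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional brain energetics and age-related covariance patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainergetics)
```

## The model

The package studies how the *spatial organization* of brain energy
metabolism changes with age, using two regional quantities acquired in one
PET/MRI session: the cerebral metabolic rate of glucose (CMRglu, from
dynamic FDG-PET via Patlak graphical analysis and the lumped-constant
scaling $CMRglu = K_i\,C_{glu}/LC$ with $LC = 0.65$) and cerebral blood
flow (CBF, from arterial spin labelling). Under the standard assumption of
spatially uniform oxygen extraction in the healthy brain, the spatial
profile of CBF proxies that of CMRO~2~, so *discordance* between the two
profiles carries information about non-oxidative glucose use.

For each subject both regional profiles are z-scored across regions and
rotated by 45 degrees:

$$
rEP = \frac{z(CBF) + z(CMRglu)}{\sqrt 2}, \qquad
rAG = \frac{z(CMRglu) - z(CBF)}{\sqrt 2}.
$$

rEP (relative energy production) is the projection onto the line of unity
— concurrence of flow and metabolism; rAG (relative aerobic glycolysis) is
the orthogonal distance from it — positive where relative glucose use
exceeds relative flow. Both are per-subject, per-region, unitless, and by
construction invariant to any per-subject global scaling or offset of
either raw modality. The rotation is an isometry: region-wise
$rEP^2 + rAG^2 = z(CBF)^2 + z(CMRglu)^2$, and within a subject
$\mathrm{corr}(rEP, rAG) = 0$ because both z inputs have unit variance.
Z-scores use the sample SD ($N-1$); any consistent choice cancels in all
downstream correlations, but the denominator is fixed for reproducibility.
Missing regional values are rejected rather than imputed — the pipeline
assumes complete regional coverage, and silent imputation would leak into
the covariance analysis.

## Age-related covariance patterns (SSM-PCA)

The age analysis asks which *combination* of regional changes best
separates younger (age ≤ 60) from older (> 60) subjects. The cutoff of 60
years splits a broad-age-range cohort into roughly equal groups while
maximizing their mean-age difference; boundary subjects go to the younger
group. The derivation follows the Scaled Subprofile Model:

1. **Residual profile.** The subjects × regions matrix is double-demeaned,
   $R = X - \bar{x}_{i\cdot} - \bar{x}_{\cdot r} + \bar{x}$, removing
   subject-global and region-mean effects exactly (row and column means of
   $R$ are zero to machine precision).
2. **PCA.** $R$ is decomposed by SVD; region weights are the right
   singular vectors, subject scores their projections, and each
   component's VAF is $100\,\sigma_k^2 / \sum\sigma^2$.
3. **Filtering.** Components enter the recombination only if they explain
   more than 5% VAF *and* separate the age groups with a two-tailed
   pooled-variance t-test p < 0.2 on their scores. The equal-variance form
   was chosen (over Welch) because group sizes and spreads are similar by
   design and the filter is intentionally permissive.
4. **Recombination.** Forward-stepwise logistic regression of older-group
   membership on the component scores, adding at each step the component
   that most lowers AIC ($2k - 2\log L$, intercept included) and stopping
   when no addition lowers it. The combined region weights are the
   coefficient-weighted sum of the selected component weights,
   renormalized to unit norm.
5. **Cross-validation.** Steps 1–4 are re-run from scratch on the training
   side of 500 random stratified 5-fold partitions (stratification by age
   group guarantees both groups in every training set, which the t filter
   needs). Candidate components are re-derived within each training fold —
   the stricter reading of fold-wise derivation — rather than fixed from
   the full data. Each fold pattern is sign-aligned to a running mean
   reference; the final pattern is the mean of the aligned fold patterns
   (renormalized — renormalization after averaging is on by default and
   recorded in the pattern file), its per-region SD quantifying stability.
   Final subject scores are the projection of the full-cohort residual
   profile onto the final weights, oriented so that pattern expression
   increases with age.

Logistic fits use plain IRLS (`glm.fit`) with a capped iteration count and
suppressed separation warnings. At a cohort size of ~24, perfect separation
is common; the deviance then collapses toward zero and AIC reduces to
$2k$, which is exactly the ranking the stepwise search needs, so no ridge
penalization is applied and the AIC always comes from the unpenalized
likelihood.

For display, unit-norm weights are standardized to SD 1 across regions and
a region is shown when $|w| - \sigma(w) > 1$; with a laterality map the
bilateral partner of any shown region is shown too. The threshold operates
on SD-standardized weights — a configurable convention, recorded with the
mask.

### What the cross-validation does and does not guard

The per-region weight SDs honestly measure *pattern stability*: a planted
rank-1 signal yields fold patterns with zero spread, and pure noise yields
large spread. The final score–age correlation, however, is computed from
an **in-sample** projection of the full cohort onto weights that were
selected for group separation. Because the younger/older split is fixed
across folds, even noise-only components that survive the filter point
systematically toward the group contrast, and the in-sample age fit is
selection-inflated. On pattern-free synthetic cohorts the final pattern
attains nominal age-fit p < 0.05 in roughly 95% of runs — so the in-sample
p-value and r² reported with a pattern must be read as descriptive, not as
calibrated inference. The package therefore pairs every SSM-PCA pattern
with PLSC permutation inference (below), which *is* calibrated (type-I
error ≈ 5–8% at nominal 5% on the same null cohorts), and the acceptance
suite measures both rates rather than hiding them.

## PLSC validation

Partial Least Squares Correlation decomposes the clinical-by-region
correlation matrix $C = Y_s^\top X_s / (n-1)$ (columns standardized; age
as-is, sex coded ±0.5 before standardization) by SVD. Brain saliences are
compared with the SSM-PCA weights by Spearman correlation; on synthetic
recovery cohorts the two methods agree to ρ > 0.9. Latent-variable
significance uses row permutation of $Y$ ($p = (1 + \#\{\sigma^{perm}_k
\ge \sigma_k\})/(n_{perm}+1)$, default 1000 permutations) and region-level
stability uses subject bootstrap (default 500 resamples) with orthogonal
Procrustes alignment to resolve sign/rotation indeterminacy; the reported
ratio is the original salience over its bootstrap SD. The exact
cross-validation scheme used with the original data is not public, so this
standard permutation/bootstrap substitution is labelled as such in the
output files.

## Disease-pattern comparison (TPR)

Externally derived disease patterns (e.g. PDRP/PDCP/ADRP) arrive as region
weights (rDRP) plus a group mean profile (rGMP), either regional or as
voxel volumes averaged over the label set. Subject expression uses the
regionalized Topographic Profile Rating: with natural-log CMRglu (the base
only rescales all scores), $rSRP = \log rCMRglu - rGMR - rGMP$ where rGMR
is the subject's mean log rate, and the score is the projection of rSRP
onto the rDRP. Subtracting rGMR makes scores exactly invariant to
per-subject global scaling; mean-centering the rDRP before projection
(the default, with a flag to disable, since the original choice is
unstated) additionally shifts all subjects by a common constant only.
Scores are not standardized — only their covariance with other expression
measures is meaningful. Spatial similarity between patterns uses Spearman's
ρ (topological similarity need not be linear), expression similarity uses
Pearson's ρ, and each six-comparison family ({rEP, rAG} × three disease
patterns) is Bonferroni-adjusted with $\min(1, 6p)$.

## Kinetic quantification

Patlak analysis regresses $C_t(t)/C_p(t)$ on
$\int_0^t C_p\,d\tau / C_p(t)$ over frames at or beyond $t^* = 20$ min
(the frames at ≥ 20 min of the 4×1, 3×2, 8×5, 1×10 min schedule; $t^*$ is
configurable since no canonical value is stated for this protocol).
Integration is trapezoidal on the plasma grid with linear interpolation to
frame mid-times — conventional choices where none are prescribed. On
noiseless two-tissue-compartment simulations over a physiological FDG
grid ($K_1 \in \{0.05, 0.1, 0.15\}$, $k_2 \in \{0.1, 0.13, 0.2\}$,
$k_3 \in \{0.04, 0.06, 0.1\}$ min⁻¹, bracketing literature gray/white
matter values), the estimated $K_i$ is within 0.4% of
$K_1 k_3/(k_2+k_3)$; slower kinetics than these leave a visible
equilibration transient at $t^* = 20$ and would need a later $t^*$.

The image-derived input function uses a simplified spatiotemporal rule:
voxels above a fraction of the global maximum-intensity projection are
candidates, then greedy removal minimizes the squared deviation between
the mean candidate curve and three late venous samples, never dropping
below a voxel floor. The constraint set of the published selection method
is not reproduced here; the greedy rule is a stand-in and is flagged as
simplified in the documentation.

The putamen subdivision solves 1-D 3-means on anterior–posterior voxel
indices *exactly* by enumerating interval boundaries over the sorted
indices. An earlier Lloyd iteration seeded at the 1/6, 3/6, 5/6 quantiles
was abandoned: on tie-heavy integer index distributions it stalls in local
optima, while the exact solution is cheap (the 1-D optimum is always a
contiguous partition), deterministic, and assigns boundary ties to the
more anterior cluster. The anterior–posterior axis is declared explicitly
in the label-volume metadata, never guessed from headers.

## The synthetic cohort generator

No subject data accompany the original study, so a generator supplies
cohorts with exactly the statistical structure the analysis assumes. The
model is log-additive: for subject $i$, region $r$, modality $m$,

$$
\log v_{irm} = g_i + b_{mr} + e_i P_{mr} + \epsilon_{irm},
$$

with per-subject global factor $g_i \sim N(0, 0.1^2)$, region baseline
$b_{mr}$, pattern expression $e_i = s\,(age_i - \overline{age})$ (plus an
optional older-group offset, default 0), and noise
$\epsilon \sim N(0, 0.3^2)$. A unit-norm planted pattern enters both
modalities with equal sign (*concordant* — an energy-production effect
that should surface in rEP only) or opposite signs (*discordant* — an
aerobic-glycolysis effect that should surface in rAG only), or not at all.
Linear values are exponentials of the log model, so global factors are
multiplicative and cancel exactly under per-subject z-scoring.

Default conditions mirror the study: 24 subjects, ages uniform on 35–80
years with the 60-year split, 97 regions grouped into eight structural
subdivisions, sex alternating (no composition is reported, so balanced is
the neutral choice and it is configurable). The remaining defaults were
fixed once, before any acceptance measurement, by a power analysis:

* **noise_sd = 0.3** (log scale) is the stated recovery condition;
* **age_slope = 0.25**/year makes the planted rank-1 signal's matrix
  singular value ($\sqrt{24}\cdot 0.25 \cdot \mathrm{sd(age)} \approx 16$)
  clear the Marchenko–Pastur noise edge
  ($0.3(\sqrt{24}+\sqrt{97}) \approx 4.4$) by ~3.7×, the regime where PCA
  recovers a spiked direction with cosine well above 0.9;
* **baseline log-SD = 0.15** with a *shared* regional shape across
  modalities (around log 30 µmol/100 g/min for CMRglu and log 45
  mL/100 g/min for CBF). Regional glucose use and perfusion are tightly
  spatially coupled in the healthy brain; sharing the shape means
  discordance arises only from planted patterns and noise, and keeps the
  z-scoring of linear-scale values (a mildly nonlinear function of the
  log-scale model) from distorting planted directions by more than ~1%.

What the generator does **not** emulate: spatially correlated noise,
scanner point-spread and partial-volume structure, registration and
segmentation error, nonlinear aging trajectories, and outlying subjects.
Passing recovery tests therefore show that the machinery finds the
structure it is designed for at a realistic size and noise level — not
that real acquisitions satisfy the model.

Dynamic data come from the irreversible two-tissue-compartment model
($\dot C_1 = K_1 C_p - (k_2+k_3) C_1$, $\dot C_2 = k_3 C_1$) integrated
numerically, driven by a gamma-variate plasma input peaking near 1 min
with a slow recirculation washout (any tabulated input is accepted). Toy
disease patterns are unit-norm Gaussian draws, optionally Gram–Schmidt
mixed with a reference to hit a requested overlap; they stand in for real
PDRP/PDCP/ADRP files, are named `synthetic-*` throughout, and carry no
anatomical meaning.

All randomness flows from one integer seed. Each stage derives a
deterministic sub-seed (documented in `derive_seed()`), and within the
cohort generator the stream order is fixed (ages, global factors, CMRglu
noise, CBF noise), so every artifact is bit-reproducible from the manifest
alone.

## Problem sizes and numerical choices

The test and acceptance workloads use the study-scale configuration
(24 × 97, 500 × 5-fold CV) for pattern recovery, and 200 pattern-free
cohorts at 25 × 5-fold CV for the null-calibration measurements — the
reduced fold count there keeps the full derivation machinery (filter,
stepwise, sign alignment, projection) while the measured quantity, a
per-cohort rejection rate, does not benefit from more averaging per
cohort. PLSC calibration uses 100–1000 permutations depending on the
resolution the check needs. Singular values below $10^{-10}$ of the
largest are treated as numerically null; degenerate inputs (constant
score vectors, zero-variance regions, empty groups, all-empty CV models)
raise errors or `NA` flags rather than silently proceeding.

## Known limitations

* The in-sample age fit of an SSM-PCA pattern is descriptive, not
  calibrated (see above); use the PLSC permutation p for inference.
* The IDIF voxel-selection rule is a simplified stand-in.
* rAG is a proxy that inherits the uniform-OEF assumption; nothing in the
  package tests that assumption.
* Voxelwise SSM-PCA is out of scope: analyses are regional, and label
  volumes are consumed, never produced (no registration or segmentation).
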