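---
title: "Evaluating cold resistance from two-temperature trait panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cold resistance from two-temperature trait panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldscore)
```

## The evaluation model

A cold-screening trial measures a panel of genotypes under two
temperatures — a control (CK, typically 22 °C) and a chilling stress
(LT, typically 10 °C) — in replicate, across a battery of traits spanning
growth, photosynthesis, membrane integrity, reactive oxygen species,
antioxidant enzymes, osmotic adjustment, and polyamine metabolism. The
package's central estimator, `coldscore()`, converts such a table into a
single comprehensive resistance score per genotype in four steps.

**Replicate means.** All quantities are defined on the per-cell
arithmetic mean across replicates, one value per genotype × treatment ×
trait. Computing stress/control ratios on means rather than on
replicate pairs avoids arbitrary replicate pairing and matches how such
trials are summarised.

**Cold-resistance coefficient.** For trait $i$ and genotype $j$,
$\mathrm{CRC}_{ij} = T_{\mathrm{LT},ij} / T_{\mathrm{CK},ij}$. The ratio
is unit-free, so the evaluation is invariant to any positive rescaling
of a trait's measurement units. It requires strictly positive control
means, which the dataset validator enforces for ratio-scale traits. The
per-trait rate change $\mathrm{RC} = 100\,(\mathrm{CRC} - 1)$ is the
same quantity on a percent scale.

**Fuzzy membership transform.** Each trait's coefficients are min–max
normalised across the panel,
$U_{ij} = (\mathrm{CRC}_{ij} - \mathrm{CRC}_{i,\min}) /
(\mathrm{CRC}_{i,\max} - \mathrm{CRC}_{i,\min})$, which maps every trait
onto $[0,1]$ with the observed extremes at exactly 0 and 1. For traits
whose increase marks damage rather than resistance the membership is
inverted, $1 - U_{ij}$, so that larger always means more resistant. The
default registry treats malondialdehyde, superoxide production, H$_2$O$_2$
content and intercellular CO$_2$ as damage markers and all other traits
as resistance-supporting. This assignment is a modelling choice — panels
and protocols differ — so the registry's `direction` column is fully
overridable, and flipping a trait's direction maps its memberships to
their complement exactly.

**Comprehensive score and classification.** The genotype score
$U_j = \tfrac1n \sum_i U_{ij}$ is the unweighted mean membership over
the $n$ traits (no PCA-loading weighting: the plain mean keeps the score
interpretable and reproducible). Genotypes are then clustered on their
membership profiles (not on $U_j$ alone, so trait-pattern differences
matter) with Ward linkage on Euclidean distances, and the tree is cut
into $k$ groups labelled type I (strongest) downward by descending mean
score.

## Tunable parameters

* `k` (default 4): number of resistance types. Four groups —
  strong/moderate/weak/sensitive — is the convention in germplasm
  screening; any $1 \le k \le$ panel size works.
* `linkage` (default Ward via `hclust`'s `ward.D2`, which applies Ward's
  criterion to untransformed Euclidean distances) and `metric` (default
  Euclidean); `average`, `complete`, `single`, Manhattan and
  correlation distances are available for sensitivity analysis, since
  clustering tools differ in their defaults and published analyses
  rarely state them.
* `sd_type` (default `"sample"`): the genetic coefficient of variation
  $\mathrm{CV_g} = \mathrm{SD}/\bar{x} \times 100$ uses the $n-1$
  standard deviation, treating the panel as a sample of germplasm; a
  population-SD option is provided.
* `traits`: the score averages over all measured traits by default; a
  subset can be supplied when only part of the battery is trusted.

## Numerical and degenerate-case choices

* A trait whose coefficients are constant across the panel has an
  undefined min–max transform. Its memberships are set to 0.5 with a
  warning: an uninformative trait should not pull any genotype's score
  toward either extreme. Real panels essentially never trigger this;
  noise-free simulations do.
* The membership inversion for damage traits is implemented as one minus
  the normalised coefficient — the only reading that keeps memberships
  in $[0,1]$.
* PCA is computed on standardised variables (an eigendecomposition of
  the Pearson correlation matrix) and retains components with
  eigenvalue strictly greater than 1. The default observation scope
  pools genotype × treatment rows (78 rows for a 39-genotype panel), so
  one PCA spans both temperatures; per-treatment and CRC-matrix scopes
  are provided because published analyses are ambiguous on this point,
  and the choice changes the eigenstructure.
* Correlation screening reports raw two-sided p-values from
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$ and counts pairs at the uncorrected
  0.05 and 0.01 thresholds, per treatment and pooled — the convention in
  this literature; no multiplicity correction is applied.
* The factorial ANOVA is fixed-effects with interaction and requires a
  balanced design (the closed-form decomposition is exact there);
  unbalanced inputs are rejected rather than silently reweighted.
* Per-trait rate-change summaries report both the mean of per-genotype
  rate changes (the default headline) and the rate change of the grand
  means; the two differ slightly and both conventions appear in
  practice.
* Cluster-label ties (identical mean scores) are broken by the lowest
  genotype index, for determinism.

## The synthetic cohort generator

`simulate_phenotypes()` emulates the statistical structure the
evaluation assumes, so every downstream stage is testable without any
external data. The model is multiplicative log-normal:

$$y_{g,t,r,i} = \mu_i \cdot G_{g,i} \cdot
  \left[m_i \, I_{g,i}\right]^{[t=\mathrm{LT}]} \cdot \varepsilon$$

* $\mu_i$: control-condition baseline in the trait's units.
* $G_{g,i}$: mean-one log-normal genotype effect with per-trait CV equal
  to the published control-condition genetic CVs (e.g. 20.58 % for
  seedling length, 4.59 % for spermine).
* $m_i = 1 + \mathrm{RC}_i/100$: the cold-effect multiplier, defaulting
  to published cohort-level effects (0.514 for seedling length, 3.219
  for MDA, 4.118 for proline, 2.837 for putrescine, 1.099 for
  root–shoot ratio, …).
* $I_{g,i} = \exp(d_i \sigma_I z_g - \sigma_I^2/2)$: the genotype ×
  temperature interaction, driven by a single latent resistance score
  $z_g$ signed by the trait direction $d_i$, so resistant genotypes are
  pulled toward the favourable end of every trait simultaneously. The
  latent scores are standardised to exact mean zero and unit variance
  across the realised cohort: the gradient is a design property of the
  simulated panel, which makes the configured multipliers realised
  cohort-level effects and keeps per-trait mean rate change within a few
  percentage points of $100(m_i - 1)$ at any panel size. Default
  interaction CV 0.05; recovery experiments that need a strong gradient
  use 0.15.
* $\varepsilon$: mean-one log-normal replicate residual, CV 0.03 — a
  free choice (within-genotype replicate dispersion is rarely
  published) representing careful greenhouse replication.

A log-normal multiplicative model is the natural choice here: all traits
are positive and ratio-scaled, and the analysis operates on ratios,
which log-normal structure keeps exactly positive and well-behaved.
Draws happen in a fixed documented order (genotype effects trait by
trait, latent scores, then residuals in table row order), so a seed
identifies one cohort bitwise.

**What the generator does not emulate.** Trait–trait correlation beyond
what the shared latent gradient induces (real batteries have strong
within-category correlation blocks); assay mechanics (conductivities,
absorbances — trait values are emitted directly); non-log-normal tails,
measurement censoring, and block/batch effects. Passing recovery tests
therefore shows the pipeline's arithmetic and ranking behaviour is
correct under the assumed structure, not that real panels satisfy that
structure.

## Problem sizes used in validation

The test suite exercises the default 39 × 29 × 2 × 3 cohort for
calibration recovery (per-trait mean rate change within 3 percentage
points of the configured effects; realised genetic CVs within 25 %
relative, averaged over 20 seeds), 500 six-genotype single-trait
simulations for the size of the genotype F-test (rejection rate in
[0.03, 0.07] at $\alpha = 0.05$ under the null), three 39-genotype
cohorts with interaction CV 0.15 for classification recovery
(|Spearman| ≥ 0.8 between type rank and latent resistance), and small
hand-computed fixtures for every closed-form quantity (sums of squares,
memberships, eigenvalues, fold changes).

## Known limitations

* The membership transform is relative to the panel: adding or removing
  a genotype changes everyone's $U_{ij}$ through the per-trait extrema.
  Scores are comparable within one evaluated panel only.
* The unweighted mean score treats a redundant block of correlated
  traits as several votes; trait-subset evaluation (`traits =`) is the
  provided mitigation.
* The four-type split depends on linkage and metric where cluster
  separation is weak; the sensitivity options exist precisely because
  dendrogram cut points are not strongly identified.
* qPCR fold changes use the plain 2^−ΔΔCt model with a single reference
  gene and no amplification-efficiency correction.
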