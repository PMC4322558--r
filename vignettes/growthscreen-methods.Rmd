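---
title: "Statistical methods of the GrowthScreen pipeline"
author: "GrowthScreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the GrowthScreen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrowthScreen)
```

# Scope

GrowthScreen implements the statistical machinery of a genome-wide
co-culture RNAi growth screen in mammary epithelial cells and of its
clinical follow-up in a large multi-centre breast-cancer cohort. The
pipeline has five analytic stages — hit calling from per-well nuclei
counts, 3D/colony assay statistics, live-cell kinetics summaries,
subtype association with a randomization null, and subtype-stratified
survival analysis — plus seeded generators that produce synthetic data
with the structure every stage assumes, so the whole pipeline is
testable without access to raw screen images or controlled-access
cohort data.

# Hit calling from per-well counts

## Quantile normalization

Per-well nuclei counts differ in distribution between plates because of
time-dependent stain degradation and other handling artefacts.
`quantileNormalize()` maps every plate's count vector onto the
cross-plate rank means: after normalization all per-plate sorted
vectors are identical (an exact property the tests assert), within-plate
rank order is preserved, and ties share the mean of their tied reference
values. Missing values are an explicit error — silent imputation would
bias the rank means. Normalization is applied across the full screen
rather than within batches; with the monotone drift model used by the
generator the two choices are equivalent up to the rank means used.

## Mixed-effects relative growth effects

`estimateEffects()` compares counts under each siRNA condition with
counts under the carrier (transfection-reagent-only) control, adjusting
for technical artefacts:

* **plate effects** enter as a plate random intercept,
* **well-position effects** enter as fixed covariates — centred row and
  column indices plus their squares, a smooth bowl/edge surface that
  captures evaporation-driven artefacts.

The model is Gaussian on the natural (quantile-normalized) count scale.
This choice follows from the estimand: the *relative effect* is the
model-estimated count under the siRNA condition divided by the
model-estimated count under control, and a log-scale model would change
that estimand from a ratio of means to a ratio of geometric means. Both
counts in the ratio are evaluated at the condition's own well
positions, so the position adjustment appears in numerator and
denominator alike and cancels from the estimand; this matters because
the true position artefact is multiplicative while the adjustment is
additive, and evaluating the ratio at a reference position instead
would push a position-dependent bias into the effects of pools seated
near plate edges. The per-condition p-value is the Wald test of the
condition contrast.

One model is fitted per *layout group* — the set of replicate plates
that share a pool-to-well layout — rather than one genome-wide joint
model. Conditions are nested within layouts (only controls recur across
layouts), so the joint model block-diagonalizes into exactly these
per-layout fits; fitting them separately scales linearly in the number
of pools. Pools whose fit fails are reported with missing effect and
excluded from the multiple-testing correction (reducing m), with a
warning; they are never silently imputed.

A pool is a **hit** when its relative effect is at most 0.25 (growth
reduced to 25% or less of control) *and* its Benjamini–Hochberg adjusted
p-value is below 0.05. Effects are ranked from smallest to largest, ties
broken by pool identifier for determinism. Secondary-screen
reproducibility (`secondaryReproducibility()`) re-applies the same two
criteria in each of two clonal lines and calls a pool reproducible if it
passes in at least one; "same magnitude of growth reduction" has no
numeric definition in common usage, so re-meeting the original criteria
is used as the operational rule.

`estimateWellEffects()` supports the artefact-assessment design in which
additional plates carry the same control condition in every well: the
per-position multiplicative adjustment is the exponentiated mean log
count per position, centred to geometric mean 1.

# 3D acinar and colony assay statistics

Fold decreases are defined as mean control count divided by mean
silenced count, so values above 1 mean growth reduction; this matches
the orientation of the packaged gene panel (large values for the
strongest 3D effects). Confidence intervals are seeded bias-corrected
percentile bootstraps over replicates (B = 2000 by default); with n = 4
replicates the bootstrap undercovers slightly, which the tests
acknowledge by asserting calibrated rather than nominal coverage. A zero
silenced mean yields an infinite fold with a one-sided interval.

Many-to-one comparisons of silenced conditions against the shared
control use Dunnett's single-step adjustment through the multivariate-t
machinery of `multcomp`, which is exact for unbalanced designs; with a
single treatment group it reduces to the two-sample t-test (an oracle
the tests exploit).

The packaged panel (`acinarPanel()`) is a curated 47-gene summary table
of the screen's validated hits: per-gene screen ranks, 3D fold decreases
(three genes lack 3D data) and the binary shRNA outcome. Its structural
counts (47 genes, 44 with 3D data, 24 shRNA-lethal) are validated at
load time. The threshold of 1.7 used for "no significant 3D reduction"
is a panel-level convention chosen strictly between the largest
non-significant (1.618) and smallest significant (1.936) fold values in
the table — a bookkeeping device, not a statistical rule. With it the
panel reproduces the accounting 47 total, 3 genes above tenfold, 4 genes
not reduced, and 43 = 47 − 4 genes required in 3D (the three genes
without 3D data count as required).

# Live-cell kinetics

Serial red-object densities (proliferation) and caspase-positive green
fractions (apoptosis) measured every 4 hours over an 84-hour window are
summarised by trapezoidal area under the curve on the raw series
(baseline subtraction is deliberately not applied). AUCs are compared by
one-way ANOVA with per-condition contrasts against the carrier control.
Rank correlations use Spearman's rho with average ranks; the
permutation test permutes the pairing of the two AUC vectors and reports
the two-sided (k+1)/(B+1) p-value, with the bound "< 1/B" when no
permutation reaches the observed statistic. Note the deliberate
asymmetry with the enrichment module below, which uses the plain k/B
convention because its reported quantities follow that convention.

# Subtype association and the randomization null

Expression is robustly centred and scaled per gene within each data
centre: r = (e − med)/igs with med the within-centre median and igs the
interquartile spread (75th − 25th percentile). Both statistics are
per-gene, per-centre; any reading in which the median is not per-gene
makes the transform dimensionally incoherent. The transform is
idempotent, and after it every gene has median 0 and igs 1 within each
centre — properties the tests assert exactly. A gene constant within a
centre has igs 0 and raises an explicit error naming the gene and
centre. For heat-map display, values are clipped to [−3, 3] so colour
scales stay comparable across genes.

Per-gene subtype association uses the Kruskal–Wallis rank test
(chi-square approximation with tie correction — exact enumeration is not
attempted at cohort scale), BH-adjusted across genes, with genes ordered
by ascending p-value (beanplot order, lexicographic tie-break).

The enrichment question — is a selected gene set unusually subtype
associated? — is answered by `enrichmentSimulation()`: draw sets of the
same size without replacement from the flagged universe (with
replacement would misstate the finite-universe null) and count draws
with at least as many flagged genes as observed. The empirical p is
exceedances/runs (k/B, no +1 correction), rounded to three decimals for
reporting; the exceedance rate provably converges to the hypergeometric
tail, which the tests use as an analytic oracle.

# Subtype-stratified survival analysis

For each gene:

1. **Dichotomization** (`binarizeExpression()`): candidate cuts at the
   15%, 25%, 50% and 75% expression quantiles; at each, a Cox model
   with the single binarized covariate is fitted and its AIC
   (−2 log partial likelihood + 2k, Breslow ties) recorded. The cut
   with minimum AIC is chosen unless the AIC range is below 3.0, in
   which case the median is used — a fallback that keeps case counts
   adequate within subtype groups. Candidates leaving fewer than
   `minEventsPerArm` (default 10) events in either arm are excluded;
   if that excludes the median itself, the fallback reverts to the
   eligible AIC minimum so the events-per-arm guarantee always holds.
2. **Stratified Cox** (`stratifiedCox()`): shared log hazard ratio for
   high vs low expression with per-subtype baseline hazards left free,
   absorbing the non-proportional hazards between subtypes; Wald 95%
   interval.
3. **Omnibus interaction test** (`omnibusInteractionTest()`): a
   likelihood-ratio comparison of Cox(biomarker × subtype) against
   Cox(subtype only). The LRT was chosen over a Wald omnibus as the
   standard test for nested Cox models. Its degrees of freedom equal
   the biomarker-related parameters, so it is powered for
   subtype-dependent reversals whose pooled marginal effect is near
   zero — the scenario the test exists for, and one the tests verify.
4. **G-rho test** (`grhoTest()`): the Harrington–Fleming weighted rank
   test with weights Ŝ(t−)^ρ, where Ŝ is the left-continuous pooled
   Kaplan–Meier estimate within each stratum; scores and variances are
   summed across strata and referred to chi-square on 1 df. ρ = 1
   upweights early events, guarding against hazards that change over
   follow-up; ρ = 0 recovers the stratified log-rank exactly, which is
   the equivalence the test suite checks against an independent
   implementation at 1e-8. Strata without events contribute nothing.

Ties use the Breslow approximation throughout — in the fits and in the
brute-force partial-likelihood oracle used by the tests — for mutual
consistency. P-values are BH-adjusted across genes within each family
(omnibus and G-rho separately), with flags at adjusted 0.05 and 0.1.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* `simulateScreen()`: 96-well plates (8 × 12), a static control column
  (carrier, nonsilencing, positive-lethal), two replicate plates per
  layout, negative-binomial counts (nuclei counts are overdispersed
  small integers) with expected value baseline × effect × plate factor ×
  well factor × drift. Plate factors are log-normal (σ = 0.15), the
  well surface is a quadratic bowl (amplitude 0.1 on the log scale,
  geometric mean 1), and drift is geometric in processing order
  ((1 − rate)^(order−1), rate 0.01 per plate) — monotone, as stain
  degradation over time is. The default effect distribution leaves most
  pools null and gives roughly one pool in nine a true effect at or
  below 0.25, matching the scale of hit fractions a genome-wide screen
  reports. The count-noise family of a real screen is not knowable from
  summary statistics; negative binomial is a modelling choice.
* `simulateCohort()`: 1,996 patients, ten subtypes, five data centres
  with location/scale batch structure, subtype-specific Weibull
  baselines with shapes 0.6–1.8 (mixing shapes is what makes hazards
  between subtypes non-proportional), a planted threshold-type
  biomarker effect, and exponential censoring whose rate is calibrated
  against the drawn death times so the expected censored fraction hits
  the target (0.5 by default).
* `simulateAssayCounts()` and `simulateTimeSeries()` provide
  negative-binomial assay counts around baseline/fold and
  logistic-growth red-density curves with a green caspase fraction that
  rises in inverse proportion to growth (coupling 1 by default, which
  reproduces a strong negative rank correlation between the two AUCs).

All generators take one explicit integer seed and no hidden state; a
fixed seed gives bitwise-identical output, and each returns its truth
table so downstream estimators can be scored against planted values.

What the generators do *not* emulate: spatially correlated transfection
failures, siRNA off-target structure, batch effects that are
non-monotone in processing order, informative censoring, and the
correlation structure of real expression panels. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to every artefact a real screen can produce.

# Numerical choices and problem sizes

* Percentages in screen accounting are rounded half-up to one decimal
  (`stagePercent()`), matching the reporting style of screen funnels.
* Bootstrap intervals are bias-corrected percentile with B = 2000 and an
  explicit seed; the confidence method behind published assay CIs is
  not standardized, so this is the package's choice.
* Dunnett adjustment delegates to `multcomp`'s multivariate-t
  computation rather than a Monte-Carlo sampler of the many-to-one t;
  the two agree to Monte-Carlo error and the former is deterministic.
* The test suite and the acceptance script run simulations at reduced
  but statistically meaningful sizes — e.g. screens of 15–400 pools,
  cohorts of 300–2,000 patients, 100-replicate recovery loops — chosen
  so each recovery or error-rate check has enough Monte-Carlo precision
  for its stated tolerance.
* Degenerate inputs fail loudly: ragged or missing count vectors,
  constant genes within a centre, all-control designs, arms without
  events, zero control counts, duplicate well keys.

# Known limitations

* Bootstrap intervals over very few units undercover: with three patient
  samples the surviving-fraction CI reaches roughly 78% rather than 95%
  coverage in simulation (a three-point bootstrap cannot do better); the
  point estimate itself is unbiased. Interpret small-n intervals as
  rough uncertainty summaries.
* The mixed model assumes Gaussian errors on normalized counts; strongly
  skewed residuals at very low counts (near-lethal wells) are handled by
  the rank-based normalization but not modelled explicitly.
* With two replicate plates per layout the plate variance component is
  weakly identified; it is retained for structure, and the estimator
  falls back to a fixed-effects fit only when a layout has a single
  plate.
* The AIC grid for dichotomization considers four quantiles only, as the
  analysis it implements prescribes; optimal-cutpoint searches over all
  thresholds would require different multiplicity control.
* `geneSurvivalAnalysis()` treats genes independently; correlated
  expression between genes is not modelled in the BH adjustment (BH is
  robust to positive dependence).
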