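---
title: "Methods: extreme-behavior classification and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extreme-behavior classification and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressbattery)
```

This vignette is the package's own account of its methods: what each
procedure computes, which knobs matter, what the synthetic generators do
and do not emulate, and the numerical choices made where the design was
genuinely open.

## The cutoff classifier

Trauma-exposed animals are phenotyped on a five-test battery. For each
test the cohort's boundary-inclusive extreme tail is taken at a fraction
`percentile` (default 0.20): the lower tail for risk-assessment time,
startle latency and percent pre-pulse inhibition, the upper tail for
home-cage activity in the non-active phase and percent of marbles buried.
An animal extreme on at least `min_extreme_tests` (default 3) of the tests
is labeled PTSD-like.

Three choices deserve spelling out:

* **Nearest-rank quantiles.** With $n$ reference values, the low-direction
  cutoff is the $\lceil qn \rceil$-th smallest value. This makes "the
  lowest 20%" a concrete animal set rather than an interpolated number,
  which matters at cohort sizes of 35–46.
* **Boundary-inclusive flags with tie expansion.** A value exactly at the
  cutoff is flagged, and so is every animal tied with it. A constant test
  column therefore flags everybody — degenerate, but well defined.
* **Reference population.** Cutoffs default to the full table passed in,
  i.e. pooled across prenatal groups within the trauma-exposed cohort.
  A `reference` selector in `battery_config()` supports an external
  reference cohort instead. Whether cutoffs should be carried over from an
  earlier cohort is not decidable from the available description;
  per-experiment cutoffs are the default here.

Missing tests exclude an animal by default; a proportional rule
(`score / n_observed >= 3/5`) is available but off, since it changes the
implicit test correlation structure of the rule. A separate
`filter_by_score()` exposes the tissue-sampling inclusion criterion (only
the most extreme animals enter molecular assays); the published wording
("threshold over 4") is ambiguous between `score > 4` and `score >= 4`,
so the threshold is a user argument rather than a constant.

Under independent continuous tests the long-run PTSD-like fraction is the
binomial tail $\sum_{k\ge3}\binom{5}{k} q^k (1-q)^{5-k} \approx 0.0579$
at $q = 0.2$; the test suite checks the classifier against this null and
against a brute-force sort-and-take oracle.

## Contingency statistics

`yates_chi_square()` computes both the continuity-corrected statistic
$\sum (\max(|O-E|-0.5,\,0))^2/E$ (clamped at zero, so equal-proportion
tables give exactly 0) and the uncorrected one. The phi coefficient is
taken from the **uncorrected** statistic: recomputation shows
$\sqrt{\chi^2_{\mathrm{uncorr}}/N}$ reproduces the published effect sizes
(0.223 on the 3/35 vs 12/46 table; 0.587 on 6/9 vs 1/10) while the
corrected statistic does not. The reported p-value is the two-sided
chi-square tail of the corrected statistic.

## Rank-based tests

`kruskal_wallis()` uses midranks with the standard tie correction
$1-\sum_t(t^3-t)/(N^3-N)$ and reports per-group mean ranks (their
size-weighted average is exactly $(N+1)/2$, an invariant the suite
checks). `dunn_pairwise()` uses pooled-midrank z statistics whose variance
carries the matching tie term; for two groups $z^2$ equals the
tie-corrected $H$ exactly, which the suite uses as an algebraic
consistency check. "Dunn's corrected" is implemented as Bonferroni over
all pairs, the only correction explicitly named alongside it.

## ANOVA and variance explained

`two_way_anova()` computes Type III (drop-term) sums of squares under
effect coding. With 6–8 animals per cell the designs are mildly
unbalanced, and Type III keeps main effects interpretable in the presence
of the reported interaction terms. Variance explained defaults to
classical $\eta^2 = SS_{\mathrm{term}}/SS_{\mathrm{total}}$ — on balanced
designs the terms plus the residual fraction sum to 1 to $10^{-10}$ —
with partial $\eta^2$ behind a flag, since published "% variance
explained" tables rarely say which flavor they used. Post-hocs are the
four simple-effect Student t-tests of the 2×2 design at a Bonferroni
threshold of $\alpha/4$.

`mixed_three_way_anova()` implements the split-plot design with two
between-subject factors and one repeated within-subject factor (the four
transcripts measured in the same amygdala sample). Between-subject terms
are tested against the subject-within-group error (Type III on subject
means, rescaled by the number of within levels); within terms against the
subject-by-within residual. No sphericity adjustment is applied by
default — with `gg = TRUE` the Greenhouse–Geisser epsilon (estimated from
the pooled within-cell covariance) scales the within-term degrees of
freedom. Subjects missing a within level are excluded with a warning
rather than imputed.

## The normality gate

`normality_gated_compare()` encodes the dispatch rule: Shapiro–Wilk on
each sample and Levene's test (absolute deviations from the mean) at
$\alpha = 0.05$; both pass → Student's t; only equal variance fails →
Welch; any normality failure → Mann–Whitney. The object records the route
and all gate p-values, because a dispatched p-value without its route is
not auditable. Zero-variance samples are treated as failing normality
(Shapiro–Wilk is undefined on them).

## Permutation of regressor residuals

For a candidate probe regressed on trauma exposure with nuisance
covariates, `permutation_regressor_residuals()` regresses the regressor
of interest on the covariates, permutes those residuals, re-orthogonalizes
after each permutation, and recomputes the partial F. The p-value uses the
add-one estimator $(1+\#\{F^\ast \ge F\})/(1+B)$, so the smallest
attainable p is $1/(B+1)$ and zero p-values cannot occur. The statistic is
computed via a QR projection rather than refitting `lm()` per permutation,
which keeps 10,000 permutations inexpensive; F is invariant to affine
transformations of the outcome, and the suite verifies both that
invariance and nominal type-I error at $\alpha = 0.05$ over 500 null
datasets.

## Molecular quantification

Relative expression follows the $2^{-\Delta\Delta C_t}$ convention with a
housekeeping reference; no amplification-efficiency correction is applied
because no efficiencies are available to apply. Knockdown efficiency is
reported under two normalizations — housekeeping (overall downregulation)
and the viral GFP reporter (downregulation per infected unit) — with
uninfected samples (no reporter signal) flagged and excluded from the
reporter route only. The infection rubric maps per-side stained areas to
scores via half-open bins $[0,5), [5,10), [10,25), [25,50), [50,\infty)$;
the published bin edges leave exactly 50 mm² undefined, and the
half-open-up convention assigns it the maximal score 5.

## The GRE scan

The proprietary position-weight matrices behind the original site
prediction are not recoverable, so the scan is a generic IUPAC consensus
matcher: the palindromic GRE `RGNACANNNTGTNCY` with a configurable
mismatch budget (default 1), both strands, case-insensitive, with an `N`
in the sequence never counting as a match. The published "nine sites"
count is therefore *not* a reproduction target — only the pipeline shape
(scan → CpG filter → signed TSS coordinates) is, and the suite exercises
it on a constructed nine-sites/one-CpG fixture. Matching delegates to
Biostrings with mismatches recounted explicitly per hit; the test oracle
is an independent per-offset enumerator. TSS-relative coordinates are
promoter-style: $-1$ immediately upstream, $+1$ at the TSS, no zero.

## The synthetic world

The generators state a world once and the tests measure it; none of their
defaults were moved after seeing test results.

* **Behavioral cohort.** A single latent susceptibility factor per animal,
  $z \sim N(0,1)$ plus a shift of `latent_effect` for prenatally stressed
  animals; each metric is a direction-signed loading on $z$ plus unit
  Gaussian noise. A shared factor is the simplest mechanism that yields
  the observed excess of multi-test extremes; no generative model is
  available to fit, so loadings and noise are conventions (loading 1,
  SD 1, i.e. 50% latent variance per test). `latent_effect = 0.8` was
  calibrated — as the parameterization prescribes — so that the default
  35/46 cohort yields long-run prevalences near 8.6% and 26.1%.
* **Expression panel.** Cell means per transcript encode the qualitative
  effect pattern (the GILZ transcript reduced by both stressors without
  interaction; GR/CRF reduced and FKBP51 raised mainly by adult trauma
  after prenatal stress), with residual SD 0.18 on a relative-expression
  scale anchored at 1. Percent methylation is a Gaussian copula on the
  standardized coupled-gene expression, squashed through the normal CDF
  onto $(0,100)$; the squash attenuates the Pearson correlation by only a
  few percent, so a target of $\rho = -0.6$ lands within its Fisher-z
  interval at $n = 200$.
* **Knockdown experiment.** Per-side areas are log-normal (median
  18 mm², log-SD 0.8), spanning the full rubric; the behavior score rises
  with total infection score only in the knockdown group, since the
  scrambled control virus infects but does not silence.
* **Human table.** 435 subjects (135 male), trauma-event counts Poisson
  with mean 4, a male-only negative expression slope per event
  ($-0.12$ SD units) and a male-only methylation–expression coupling on
  the logit scale (betas in $(0,1)$ by construction). The female
  expression slope is exactly 0, which is what makes the sex-stratified
  recovery test a sign-pattern test rather than a magnitude test.

What a green suite does **not** establish: the generators are Gaussian and
single-factor, so they say nothing about skewed behavioral metrics, litter
effects, batch structure, or array preprocessing — all deliberately out of
scope. Quantities whose inputs were never published (human correlation
magnitudes, CORT mean-rank group sizes, the exact variance-explained
percentages, the MatInspector site count) are covered by property and
calibration tests, not by value reproduction.

## Reproducibility choices

Every generator takes one seed and splits it into fixed per-stream
sub-seeds (latent, per-test noise, methylation, covariates …), so adding a
stream never perturbs the draws of existing streams, and seeded calls
save and restore the global RNG state. `run_pipeline()` derives all its
stream seeds from a single master seed and stamps every report with that
seed plus an FNV-1a fingerprint of the configuration; the same
configuration reproduces every number exactly.
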