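Package: stressbattery
Title: Extreme-Behavior Classification and Association Statistics for
    Stress-Susceptibility Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phenotyping stress-susceptible subpopulations in
    rodent trauma cohorts and for the statistics that accompany such
    studies.  Implements the cutoff-based extreme-behavior classifier
    (per-test percentile boundaries, direction-aware extreme flags and a
    k-of-n "PTSD-like" label), 2x2 contingency statistics with Yates
    continuity correction and the phi effect size, rank-based group
    tests (Kruskal-Wallis with tie correction, Dunn pairwise
    comparisons), variance-partitioning two-way and split-plot
    repeated-measures ANOVA with eta-squared, a normality-gated
    two-group comparison dispatcher, permutation-of-regressor-residuals
    association testing, relative qPCR quantification (delta-delta-Ct,
    dual-reference knockdown efficiency), an infection-area scoring
    rubric, a CpG-filtered glucocorticoid response element promoter
    scan, and synthetic cohort generators that reproduce the statistical
    structure the downstream analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
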