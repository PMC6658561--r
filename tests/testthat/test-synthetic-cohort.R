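test_that("cohort simulation is deterministic given a seed", {
  p <- cohort_params(seed = 1001)
  c1 <- simulate_behavior_cohort(p)
  c2 <- simulate_behavior_cohort(p)
  expect_identical(c1, c2)
  c3 <- simulate_behavior_cohort(cohort_params(seed = 1002))
  expect_false(identical(c1$latent, c3$latent))
  # default design mirrors the trauma-exposed cohort sizes
  expect_equal(as.vector(table(c1$prenatal)), c(35, 46))
  expect_true(all(c1$exposure == "trauma"))
})

test_that("zero loadings give i.i.d. metrics at the independence null", {
  p <- cohort_params(n_per_group = c(control_trauma = 300L,
                                     stressed_trauma = 300L),
                     latent_effect = 0, test_loadings = rep(0, 5),
                     seed = 1003)
  co <- simulate_behavior_cohort(p)
  mets <- as.matrix(co[, c("risk_assessment", "startle_latency", "ppi",
                           "homecage_activity", "marbles_buried")])
  cors <- cor(mets)
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.15))
  # classifier prevalence near the Binomial(5, 0.2) tail
  frac <- mean(classify_cohort(co)$result$label == "PTSD-like")
  p_tail <- sum(dbinom(3:5, 5, 0.2))
  expect_lt(abs(frac - p_tail), 0.04)
})

test_that("parameter validation rejects degenerate cohorts", {
  expect_error(cohort_params(n_per_group = c(control_trauma = 0)),
               "positive")
  expect_error(cohort_params(n_per_group = c(bad_cell = 5)), "design cells")
  expect_error(cohort_params(noise_sd = 0), "noise_sd")
  expect_error(cohort_params(target_prevalences = c(control = 1.2)),
               "\\[0, 1\\]")
})

test_that("zero-noise panel reproduces the specified cell means", {
  design <- data.frame(
    prenatal = factor(rep(c("control", "stressed"), each = 6),
                      levels = c("control", "stressed")),
    exposure = factor(rep(rep(c("no_trauma", "trauma"), each = 3), 2),
                      levels = c("no_trauma", "trauma")))
  pp <- panel_params(residual_sd = 1e-9, seed = 1005)
  panel <- simulate_expression_panel(design, pp)
  for (g in rownames(pp$cell_means)) {
    cm <- tapply(panel[[g]],
                 paste(design$prenatal, design$exposure, sep = "_"), mean)
    expect_equal(cm[colnames(pp$cell_means)], pp$cell_means[g, ],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(
    simulate_expression_panel(
      data.frame(prenatal = "odd", exposure = "trauma"), pp),
    "cell")
})

test_that("methylation coupling hits its target correlation and bounds", {
  design <- data.frame(
    prenatal = factor(rep("control", 200), c("control", "stressed")),
    exposure = factor(rep("trauma", 200), c("no_trauma", "trauma")))
  panel <- simulate_expression_panel(design,
                                     panel_params(seed = 1007))
  expect_true(all(panel$percent_methylation >= 0 &
                    panel$percent_methylation <= 100))
  r <- cor(panel$percent_methylation, panel$GILZ)
  expect_lt(abs(atanh(r) - atanh(-0.6)), 1.96 / sqrt(197))

  # uncoupled methylation stays below the null comparison quantile mostly
  hits <- vapply(1:60, function(i) {
    pan <- simulate_expression_panel(
      design[1:80, ], panel_params(meth_coupling_r = 0, seed = 2000 + i))
    abs(cor(pan$percent_methylation, pan$GILZ)) < qnorm(0.975) / sqrt(80 - 3)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("knockdown simulation couples score to infection in KD only", {
  kd1 <- simulate_kd_experiment(seed = 1009)
  expect_identical(kd1, simulate_kd_experiment(seed = 1009))
  expect_equal(as.vector(table(kd1$group)), c(10, 9))
  expect_true(all(kd1$total == kd1$left_score + kd1$right_score))

  # large slope, small noise: strong correlation in the KD group
  strong <- simulate_kd_experiment(n_kd = 8, score_slope = 1,
                                   noise_sd = 0.2, seed = 1011)
  kd_rows <- strong[strong$group == "KD", ]
  expect_gte(cor(kd_rows$total, kd_rows$ptsd_score), 0.8)

  # zero slope: no systematic coupling (averaged over replicates)
  rs <- vapply(1:40, function(i) {
    d <- simulate_kd_experiment(n_kd = 30, score_slope = 0, seed = 3000 + i)
    k <- d[d$group == "KD", ]
    suppressWarnings(cor(k$total, k$ptsd_score))
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
  expect_error(simulate_kd_experiment(n_kd = 0), ">= 1")
})

test_that("human table simulation respects bounds, types and the sex split", {
  h <- simulate_human_table(human_table_params(seed = 1013))
  expect_identical(h, simulate_human_table(human_table_params(seed = 1013)))
  expect_equal(nrow(h), 435L)
  expect_equal(sum(h$sex == "male"), 135L)
  expect_true(all(h$meth_beta > 0 & h$meth_beta < 1))
  expect_true(all(h$tei >= 0 & h$tei == round(h$tei)))

  expect_error(
    simulate_human_table(human_table_params(
      tei_distribution = function(n) rnorm(n), seed = 1)),
    "non-negative integer")
  expect_error(human_table_params(n_subjects = 3), "covariate count")
})

test_that("null human slopes give null-consistent stratified p-values", {
  set.seed(1015)
  pvals <- vapply(1:40, function(i) {
    h <- simulate_human_table(human_table_params(
      n_subjects = 120, expr_tei_slope_male = 0, seed = 4000 + i))
    res <- sex_stratified_association(h, "expression", "tei")
    res$p[res$stratum == "male"]
  }, numeric(1))
  expect_lte(mean(pvals <= 0.05), 0.2)
  expect_gt(mean(pvals), 0.3)
})
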