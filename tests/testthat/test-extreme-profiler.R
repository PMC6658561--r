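make_table <- function(values) {
  data.frame(animal_id = sprintf("a%02d", seq_along(values)),
             risk_assessment = values)
}

one_test_config <- function(direction, percentile = 0.2) {
  battery_config(list(test_spec("risk_assessment", direction = direction)),
                 min_extreme_tests = 1, percentile = percentile)
}

test_that("nearest-rank cutoffs flag the boundary-inclusive extreme set", {
  tab <- make_table(1:10)
  low <- compute_cutoffs(tab, one_test_config("low"))
  expect_equal(low$cutoff, 2)
  expect_equal(low$n_reference, 10L)
  expect_equal(unname(which(flag_extremes(tab, low)[, 1])), c(1L, 2L))

  high <- compute_cutoffs(tab, one_test_config("high"))
  expect_equal(high$cutoff, 9)
  expect_equal(unname(which(flag_extremes(tab, high)[, 1])), c(9L, 10L))

  # a value exactly at the cutoff is flagged (boundary inclusive)
  tab2 <- make_table(c(1, 2, 2, 2, 5, 6, 7, 8, 9, 10))
  cut2 <- compute_cutoffs(tab2, one_test_config("low"))
  expect_equal(cut2$cutoff, 2)
  expect_equal(sum(flag_extremes(tab2, cut2)[, 1]), 4L)

  # constant column: everyone ties at the boundary
  tabc <- make_table(rep(3, 8))
  cutc <- compute_cutoffs(tabc, one_test_config("low"))
  expect_equal(cutc$cutoff, 3)
  expect_true(all(flag_extremes(tabc, cutc)[, 1]))
})

test_that("cutoff computation validates its inputs", {
  cfg <- battery_config(list(test_spec("absent_metric", direction = "low")),
                        min_extreme_tests = 1)
  expect_error(compute_cutoffs(make_table(1:5), cfg), "absent_metric")
  tab <- make_table(c(NA, NA, NA))
  expect_error(compute_cutoffs(tab, one_test_config("low")),
               "non-missing")
  expect_error(battery_config(list(test_spec("x")), min_extreme_tests = 1,
                              percentile = 0.6),
               "percentile")
  expect_error(battery_config(list(test_spec("x")), min_extreme_tests = 2),
               "min_extreme_tests")
})

test_that("k-of-n labeling follows the 3-of-5 rule and handles missing tests", {
  cfg <- default_battery()
  flags <- rbind(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                 c(TRUE, TRUE, FALSE, FALSE, FALSE),
                 c(TRUE, TRUE, TRUE, TRUE, TRUE),
                 c(TRUE, TRUE, NA, FALSE, FALSE))
  colnames(flags) <- names(cfg$tests)
  res <- classify_battery(flags, cfg)
  expect_equal(as.character(res$label),
               c("PTSD-like", "resilient", "PTSD-like", NA))
  expect_equal(res$score, c(3L, 2L, 5L, 2L))
  expect_equal(res$n_tests_observed, c(5L, 5L, 5L, 4L))

  # proportional fallback rescales the threshold to observed tests
  flags2 <- rbind(c(TRUE, TRUE, TRUE, NA, NA))
  colnames(flags2) <- names(cfg$tests)
  res2 <- classify_battery(flags2, cfg, incomplete = "proportional")
  expect_equal(as.character(res2$label), "PTSD-like")

  expect_error(classify_battery(flags[0, , drop = FALSE], cfg), "no animals")
})

test_that("flag matrices agree with the sort-and-take brute-force oracle", {
  set.seed(11)
  cfg <- default_battery()
  for (i in 1:25) {
    n <- sample(10:200, 1)
    tab <- data.frame(animal_id = seq_len(n),
                      risk_assessment = rnorm(n),
                      startle_latency = round(rnorm(n), 1),  # ties
                      ppi = rnorm(n),
                      homecage_activity = rpois(n, 20),       # heavy ties
                      marbles_buried = rnorm(n))
    cuts <- compute_cutoffs(tab, cfg)
    expect_equal(unname(flag_extremes(tab, cuts)),
                 unname(oracle_flags(tab, cfg)))
  }
})

test_that("scores are monotone in the percentile and row-order invariant", {
  set.seed(21)
  n <- 80
  tab <- data.frame(animal_id = seq_len(n),
                    risk_assessment = rnorm(n), startle_latency = rnorm(n),
                    ppi = rnorm(n), homecage_activity = rnorm(n),
                    marbles_buried = rnorm(n))
  score_at <- function(q, t = tab) {
    cls <- classify_cohort(t, default_battery(percentile = q))
    cls$result$score
  }
  s10 <- score_at(0.10); s20 <- score_at(0.20); s30 <- score_at(0.30)
  expect_true(all(s10 <= s20))
  expect_true(all(s20 <= s30))

  perm <- sample(n)
  expect_equal(score_at(0.2, tab[perm, ]), score_at(0.2)[perm])
})

test_that("prevalence tables match group marginals and relabeling swaps rows", {
  lab <- factor(rep(c("PTSD-like", "resilient"), c(15, 66)),
                levels = c("resilient", "PTSD-like"))
  grp <- rep(c("control", "stressed"), c(35, 46))
  tab <- prevalence_table(lab, grp)
  expect_equal(rowSums(tab), c(control = 35, stressed = 46))
  swapped <- prevalence_table(lab, factor(grp,
                                          levels = c("stressed", "control")))
  expect_equal(unname(swapped), unname(tab[2:1, ]))
  expect_error(prevalence_table(lab, rep(c("a", "b", "c"), 27)),
               "stratify")
  expect_equal(unname(prevalence(tab, percent = TRUE)),
               unname(round(100 * tab[, 1] / rowSums(tab))))
})

test_that("null calibration approaches the Binomial(5, q) tail", {
  # independent continuous tests: long-run PTSD-like fraction near the
  # analytic 3-of-5 tail at q = 0.2 (~0.0579)
  set.seed(31)
  p_tail <- sum(dbinom(3:5, 5, 0.2))
  n <- 200; reps <- 60
  frac <- mean(vapply(seq_len(reps), function(i) {
    tab <- data.frame(risk_assessment = rnorm(n), startle_latency = rnorm(n),
                      ppi = rnorm(n), homecage_activity = rnorm(n),
                      marbles_buried = rnorm(n))
    mean(classify_cohort(tab, default_battery())$result$label == "PTSD-like")
  }, numeric(1)))
  expect_lt(abs(frac - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / (n * reps)))
})

test_that("score filter retains only sufficiently extreme animals", {
  cfg <- default_battery()
  flags <- matrix(rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 3), 3, 5,
                  byrow = TRUE)
  flags[2, ] <- FALSE
  colnames(flags) <- names(cfg$tests)
  res <- classify_battery(flags, cfg)
  expect_equal(nrow(filter_by_score(res, 4)), 2L)
})
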