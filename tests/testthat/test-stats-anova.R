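balanced_2x2 <- function(cell_means, n, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- factor(rep(rep(c("a1", "a2"), each = n), 2))
  b <- factor(rep(c("b1", "b2"), each = 2 * n))
  mu <- cell_means[cbind(as.integer(a), as.integer(b))]
  list(y = mu + rnorm(length(mu), sd = sd), a = a, b = b)
}

test_that("Type III SS matches the least-squares drop-term oracle", {
  # zero-noise constructed cell means, balanced and unbalanced
  d <- balanced_2x2(matrix(c(10, 10, 10, 20), 2), n = 6)
  fit <- two_way_anova(d$y, d$a, d$b)
  ora <- oracle_two_way_ss(d$y, d$a, d$b)
  expect_equal(fit$table$ss, unname(ora), tolerance = 1e-8)

  set.seed(41)
  for (i in 1:10) {
    n_cell <- sample(6:8, 4, replace = TRUE)
    a <- factor(rep(rep(c("a1", "a2"), 2), n_cell))
    b <- factor(rep(c("b1", "b1", "b2", "b2"), n_cell))
    y <- rnorm(sum(n_cell), mean = 2 * (a == "a2") * (b == "b2"))
    fit <- two_way_anova(y, a, b)
    expect_equal(fit$table$ss, unname(oracle_two_way_ss(y, a, b)),
                 tolerance = 1e-8)
  }
})

test_that("classical eta-squared terms sum to one on balanced designs", {
  d <- balanced_2x2(matrix(c(1, 2, 3, 5), 2), n = 8, sd = 1, seed = 43)
  fit <- two_way_anova(d$y, d$a, d$b)
  expect_equal(sum(fit$table$var_explained), 1, tolerance = 1e-10)
  # partial eta-squared flavor is available and differs
  fit_p <- two_way_anova(d$y, d$a, d$b, es = "partial_eta2")
  expect_false(isTRUE(all.equal(fit$table$var_explained[1],
                                fit_p$table$var_explained[1])))
})

test_that("a pure main effect leaves the other terms near zero", {
  d <- balanced_2x2(matrix(c(0, 5, 0, 5), 2), n = 10, sd = 1e-6, seed = 47)
  fit <- two_way_anova(d$y, d$a, d$b)
  ve <- setNames(fit$table$var_explained, fit$table$term)
  expect_gt(ve[["A"]], 0.999)
  expect_lt(ve[["B"]], 1e-6)
  expect_lt(ve[["A:B"]], 1e-6)
})

test_that("observation order does not change the table; empty cells error", {
  d <- balanced_2x2(matrix(c(1, 4, 2, 6), 2), n = 7, sd = 1, seed = 53)
  fit <- two_way_anova(d$y, d$a, d$b)
  perm <- sample(length(d$y))
  fit2 <- two_way_anova(d$y[perm], d$a[perm], d$b[perm])
  expect_equal(fit$table, fit2$table)
  keep <- !(d$a == "a1" & d$b == "b1")
  expect_error(two_way_anova(d$y[keep], d$a[keep], d$b[keep]), "empty")
})

test_that("post-hoc simple effects find the planted contrast", {
  d <- balanced_2x2(matrix(c(0, 0, 0, 4), 2), n = 8, sd = 0.5, seed = 59)
  fit <- two_way_anova(d$y, d$a, d$b)
  expect_equal(nrow(fit$posthoc), 4L)
  expect_true(all(fit$posthoc$p_bonferroni >= fit$posthoc$p))
  # the a2-stratum comparison (b1 vs b2) carries the planted effect
  hit <- fit$posthoc[fit$posthoc$stratum == "A = a2" &
                       fit$posthoc$comparison == "b1 vs b2", ]
  expect_true(hit$significant)
})

split_plot_data <- function(n_cell = 4, k = 4, sd = 0, seed = NULL,
                            subj_sd = 0) {
  if (!is.null(seed)) set.seed(seed)
  n_subj <- 4 * n_cell
  a <- rep(rep(c("a1", "a2"), each = n_cell), 2)
  b <- rep(c("b1", "b2"), each = 2 * n_cell)
  subj <- sprintf("s%02d", seq_len(n_subj))
  subj_eff <- rnorm(n_subj, sd = subj_sd)
  d <- expand.grid(subject = subj, w = paste0("g", seq_len(k)),
                   stringsAsFactors = FALSE)
  d$a <- a[match(d$subject, subj)]
  d$b <- b[match(d$subject, subj)]
  gi <- as.integer(factor(d$w))
  d$y <- 0.5 * gi + (d$a == "a2") * 1 + (d$b == "b2") * gi * 0.3 +
    subj_eff[match(d$subject, subj)] + rnorm(nrow(d), sd = sd)
  d
}

test_that("split-plot SS decomposition matches the cell-mean oracle", {
  for (seed in c(61, 67)) {
    d <- split_plot_data(n_cell = 4, sd = 0.7, subj_sd = 1, seed = seed)
    fit <- mixed_three_way_anova(d$y, d$subject, d$a, d$b, d$w)
    ora <- oracle_split_plot_ss(d$y, d$subject, d$a, d$b, d$w)
    got <- setNames(fit$table$ss, fit$table$term)
    expect_equal(unname(got[c("A", "B", "A:B")]),
                 unname(ora[c("A", "B", "AB")]), tolerance = 1e-8)
    expect_equal(unname(got[["Subjects (error)"]]),
                 unname(ora[["subj_err"]]), tolerance = 1e-8)
    expect_equal(unname(got[c("W", "A:W", "B:W", "A:B:W")]),
                 unname(ora[c("W", "AW", "BW", "ABW")]), tolerance = 1e-8)
    expect_equal(unname(got[["Subjects x Within (error)"]]),
                 unname(ora[["swg"]]), tolerance = 1e-8)
  }
})

test_that("within-only effects leave the between stratum flat", {
  d <- split_plot_data(n_cell = 4, sd = 0.01, subj_sd = 0, seed = 71)
  # remove the between-subject effect, keep the gene profile
  d$y <- d$y - (d$a == "a2") * 1
  fit <- mixed_three_way_anova(d$y, d$subject, d$a, d$b, d$w)
  tab <- fit$table
  # the between factor carries no signal (null F), the gene profile is huge
  expect_gt(tab$p[tab$term == "A"], 0.05)
  expect_lt(tab$var_explained[tab$term == "A"], 0.01)
  expect_gt(tab$F[tab$term == "W"], 100)
})

test_that("duplicating every subject doubles all sums of squares", {
  d <- split_plot_data(n_cell = 3, sd = 0.8, subj_sd = 0.7, seed = 73)
  fit1 <- mixed_three_way_anova(d$y, d$subject, d$a, d$b, d$w)
  d2 <- rbind(d, transform(d, subject = paste0(subject, "_dup")))
  fit2 <- mixed_three_way_anova(d2$y, d2$subject, d2$a, d2$b, d2$w)
  expect_equal(fit2$table$ss, 2 * fit1$table$ss, tolerance = 1e-8)
})

test_that("incomplete subjects are excluded with a warning", {
  d <- split_plot_data(n_cell = 3, sd = 0.5, subj_sd = 0.5, seed = 79)
  d_miss <- d[!(d$subject == "s01" & d$w == "g2"), ]
  expect_warning(fit <- mixed_three_way_anova(d_miss$y, d_miss$subject,
                                              d_miss$a, d_miss$b, d_miss$w),
                 "excluded")
  expect_equal(fit$n_subjects, 11L)
})
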