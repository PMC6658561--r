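#' Normality-gated two-group comparison
#'
#' Dispatch rule used throughout the cohort analyses: each sample is tested
#' for departure from normality (Shapiro-Wilk, alpha = 0.05) and the two
#' samples for equal variance (Levene's test on absolute deviations from
#' the group mean, alpha = 0.05).  Both normal and homoscedastic: Student's
#' t-test.  Normal but heteroscedastic: Welch's t.  Any normality failure:
#' Mann-Whitney U.  The report records the route taken.
#'
#' @param x,y Numeric samples, each with at least 3 values.
#' @param alpha Gate level for the Shapiro-Wilk and Levene tests.
#' @return Object of class `gated_comparison`: `route` (`"student_t"`,
#'   `"welch_t"` or `"mann_whitney"`), `statistic`, `p`, `estimate`
#'   (difference in means or in location), and the gate p-values
#'   (`shapiro_x`, `shapiro_y`, `levene`).
#' @export
normality_gated_compare <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("each sample needs n >= 3 (Shapiro-Wilk undefined below that)",
         call. = FALSE)
  }
  sw <- function(v) {
    if (stats::sd(v) == 0) return(0)      # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  p_sx <- sw(x); p_sy <- sw(y)
  p_lev <- .levene_p(x, y)
  normal <- p_sx > alpha && p_sy > alpha
  if (!normal) {
    wt <- suppressWarnings(stats::wilcox.test(x, y, conf.int = TRUE,
                                              exact = FALSE))
    route <- "mann_whitney"
    res <- list(statistic = unname(wt$statistic), p = wt$p.value,
                estimate = unname(wt$estimate))
  } else if (p_lev <= alpha) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    route <- "welch_t"
    res <- list(statistic = unname(tt$statistic), p = tt$p.value,
                estimate = unname(diff(rev(tt$estimate))))
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    route <- "student_t"
    res <- list(statistic = unname(tt$statistic), p = tt$p.value,
                estimate = unname(diff(rev(tt$estimate))))
  }
  structure(c(list(route = route), res,
              list(shapiro_x = p_sx, shapiro_y = p_sy, levene = p_lev,
                   n = c(length(x), length(y)), alpha = alpha)),
            class = "gated_comparison")
}

# Levene's test (center = mean) for two samples via one-way ANOVA on
# absolute deviations.
.levene_p <- function(x, y) {
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  if (stats::sd(z) == 0) return(1)
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped); at least 3 complete pairs and non-zero variance in each.
#' @return Object of class `correlation_result` with `r`, `p` (two-sided),
#'   `df` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  structure(list(r = r, p = p, df = df, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, P = %.4g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' @export
print.gated_comparison <- function(x, ...) {
  cat(sprintf("Two-group comparison via %s: statistic = %.3f, P = %.4g\n",
              x$route, x$statistic, x$p))
  cat(sprintf("  gates: Shapiro-Wilk p = %.3f / %.3f, Levene p = %.3f (alpha = %.2f)\n",
              x$shapiro_x, x$shapiro_y, x$levene, x$alpha))
  invisible(x)
}

#' Sex-stratified association analysis
#'
#' Splits the table by a stratum column (typically sex) and, within each
#' stratum, correlates the outcome with the predictor
#' ([pearson_correlation()]), or runs the covariate-adjusted permutation
#' test ([permutation_regressor_residuals()]) when covariate columns are
#' supplied.  Strata with fewer than 3 usable rows are skipped with a
#' warning.
#'
#' @param data Data frame of subjects.
#' @param outcome,predictor Column names of the outcome and the predictor
#'   of interest.
#' @param strata Column name of the stratifying factor (default `"sex"`).
#' @param covariates Optional character vector of covariate column names;
#'   switches to the permutation route.
#' @param n_perm,seed Passed to [permutation_regressor_residuals()].
#' @return Data frame with one row per stratum: `stratum`, `n`, and either
#'   `r`/`p` or `F`/`p_parametric`/`p_permutation`.
#' @export
sex_stratified_association <- function(data, outcome, predictor,
                                       strata = "sex", covariates = NULL,
                                       n_perm = 999, seed = NULL) {
  stopifnot(is.data.frame(data),
            all(c(outcome, predictor, strata, covariates) %in% names(data)))
  lev <- levels(as.factor(data[[strata]]))
  if (length(lev) < 2L) stop("strata column needs >= 2 levels", call. = FALSE)
  rows <- lapply(lev, function(s) {
    d <- data[data[[strata]] == s, , drop = FALSE]
    d <- d[stats::complete.cases(d[, c(outcome, predictor, covariates)]), ,
           drop = FALSE]
    if (nrow(d) < 3L) {
      warning("stratum '", s, "' has fewer than 3 usable rows: skipped")
      return(NULL)
    }
    if (is.null(covariates)) {
      cr <- pearson_correlation(d[[predictor]], d[[outcome]])
      data.frame(stratum = s, n = cr$n, r = cr$r, p = cr$p,
                 stringsAsFactors = FALSE)
    } else {
      pr <- permutation_regressor_residuals(
        y = d[[outcome]], covariates = d[, covariates, drop = FALSE],
        regressor = d[[predictor]], n_perm = n_perm, seed = seed)
      data.frame(stratum = s, n = nrow(d), F = pr$F_observed,
                 slope = pr$slope, p_parametric = pr$p_parametric,
                 p_permutation = pr$p_permutation, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
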