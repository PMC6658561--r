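#' Yates-corrected chi-square and phi for a 2x2 table
#'
#' The continuity-corrected statistic is
#' \eqn{\sum (\max(|O - E| - 0.5, 0))^2 / E} with 1 degree of freedom; the
#' correction is clamped at zero so tables with identical proportions give
#' a statistic of exactly 0.  The phi effect size is computed from the
#' *uncorrected* statistic, \eqn{\phi = \sqrt{\chi^2_{uncorr} / N}}.
#'
#' @param table 2x2 matrix of non-negative integer counts (e.g. a
#'   `contingency_2x2` from [prevalence_table()]).
#' @return Object of class `chisq_2x2` with `statistic_corrected`,
#'   `statistic_uncorrected`, `df`, `p` (two-sided, from the corrected
#'   statistic) and `phi`.
#' @examples
#' yates_chi_square(matrix(c(3, 12, 32, 34), 2))
#' @export
yates_chi_square <- function(table) {
  m <- unclass(as.matrix(table))
  if (!all(dim(m) == 2L)) stop("`table` must be 2x2", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  N <- sum(m)
  if (N < 1) stop("empty table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal: expected counts undefined", call. = FALSE)
  }
  E <- outer(rowSums(m), colSums(m)) / N
  stat_unc <- sum((m - E)^2 / E)
  stat_cor <- sum(pmax(abs(m - E) - 0.5, 0)^2 / E)
  structure(
    list(statistic_corrected = stat_cor,
         statistic_uncorrected = stat_unc,
         df = 1L,
         p = stats::pchisq(stat_cor, df = 1, lower.tail = FALSE),
         phi = sqrt(stat_unc / N),
         n = N,
         table = m),
    class = "chisq_2x2")
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  cat("2x2 chi-square with continuity correction\n")
  cat(sprintf("  X2(1) = %.3f (uncorrected %.3f), P = %.4g, phi = %.3f, N = %d\n",
              x$statistic_corrected, x$statistic_uncorrected, x$p, x$phi, x$n))
  invisible(x)
}
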