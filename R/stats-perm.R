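#' Permutation-of-regressor-residuals association test
#'
#' Covariate-adjusted permutation test for a single regressor of interest
#' in a linear model.  The regressor is first regressed on the covariates;
#' its residuals carry the part of the regressor not explained by the
#' covariates.  The observed statistic is the partial F for the regressor
#' in `y ~ covariates + regressor`.  Under the null the regressor residuals
#' are exchangeable, so they are permuted, the model refit, and the F
#' recomputed; the permutation p-value uses the add-one estimator
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, which can never be zero.
#'
#' The F statistic is invariant to affine transformations of `y`, so the
#' permutation p inherits that invariance.
#'
#' @param y Numeric outcome.
#' @param covariates Data frame or matrix of nuisance covariates (factors
#'   are expanded; an intercept is always included).
#' @param regressor Numeric regressor of interest.
#' @param n_perm Number of permutations (>= 99; analyses of the human
#'   candidate-gene table used 10,000).
#' @param seed Optional integer seed making the permutation stream
#'   reproducible.
#' @return Object of class `perm_assoc` with `F_observed`, `slope`,
#'   `p_parametric` (F-distribution reference), `p_permutation` and
#'   `n_permutations`.
#' @export
permutation_regressor_residuals <- function(y, covariates, regressor,
                                            n_perm = 10000L, seed = NULL) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  y <- as.numeric(y)
  z <- as.numeric(regressor)
  n <- length(y)
  stopifnot(length(z) == n)
  if (stats::sd(z) == 0) stop("constant regressor", call. = FALSE)
  X <- if (is.matrix(covariates)) cbind(1, covariates)
       else stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(X) != n) stop("covariate rows do not match y", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariates", call. = FALSE)
  df2 <- n - qx$rank - 1L
  if (df2 < 1L) stop("not enough residual degrees of freedom", call. = FALSE)

  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  perp <- function(v) v - Q %*% crossprod(Q, v)
  y_perp <- perp(y)
  ssy <- sum(y_perp^2)
  r_z <- perp(z)
  if (sum(r_z^2) < 1e-12 * sum(z^2)) {
    stop("regressor is collinear with the covariates", call. = FALSE)
  }
  # partial F for adding v to the covariate model (v re-orthogonalized,
  # since permuted residuals are no longer orthogonal to the covariates)
  fstat <- function(v_perp) {
    ssv <- sum(v_perp^2)
    if (ssv < 1e-12) return(0)
    ss_reg <- sum(y_perp * v_perp)^2 / ssv
    rssf <- ssy - ss_reg
    if (rssf <= 0) return(Inf)
    ss_reg / (rssf / df2)
  }
  F_obs <- fstat(r_z)
  slope <- sum(y_perp * r_z) / sum(r_z^2)

  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  F_perm <- vapply(seq_len(n_perm), function(i) {
    fstat(perp(r_z[sample.int(n)]))
  }, numeric(1))
  p_perm <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)

  structure(list(F_observed = F_obs, slope = slope,
                 p_parametric = stats::pf(F_obs, 1, df2, lower.tail = FALSE),
                 p_permutation = p_perm, n_permutations = n_perm,
                 df = c(1L, df2)),
            class = "perm_assoc")
}

#' @export
print.perm_assoc <- function(x, ...) {
  cat(sprintf(
    "Permutation of regressor residuals: F(1,%d) = %.3f, slope = %.4g\n",
    x$df[2], x$F_observed, x$slope))
  cat(sprintf("  parametric P = %.4g; permutation P = %.4g (%d permutations)\n",
              x$p_parametric, x$p_permutation, x$n_permutations))
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
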