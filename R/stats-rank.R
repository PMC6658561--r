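#' Kruskal-Wallis H test with tie correction
#'
#' Midrank-based H statistic,
#' \eqn{H = [12 / (N(N+1)) \sum_i n_i \bar R_i^2 - 3(N+1)] / (1 - \sum_t (t^3 - t)/(N^3 - N))},
#' with per-group mean ranks reported (as printed for basal CORT
#' comparisons across exposure groups).
#'
#' @param x Either a list of numeric vectors (one per group) or a numeric
#'   vector of values.
#' @param g Group labels, required when `x` is a vector.
#' @return Object of class `kruskal_result` with `H`, `df`, `p`,
#'   `mean_ranks` and group sizes `n`.
#' @export
kruskal_wallis <- function(x, g = NULL) {
  groups <- .as_group_list(x, g)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)  # midranks
  mean_ranks <- tapply(r, gi, mean)
  names(mean_ranks) <- names(groups)
  n_i <- lengths(groups)
  H_raw <- 12 / (N * (N + 1)) * sum(n_i * mean_ranks^2) - 3 * (N + 1)
  tie_tab <- table(values)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (C <= 0) {
    warning("all values identical: H set to 0")
    H <- 0
  } else {
    H <- H_raw / C
  }
  df <- length(groups) - 1L
  structure(list(H = H, df = df,
                 p = stats::pchisq(H, df, lower.tail = FALSE),
                 mean_ranks = mean_ranks, n = n_i, N = N),
            class = "kruskal_result")
}

#' Dunn pairwise post-hoc comparisons
#'
#' Dunn z statistics from pooled midranks with tie correction,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(\frac{N(N+1)}{12} -
#' \frac{\sum_t (t^3 - t)}{12(N-1)}) (1/n_i + 1/n_j)}},
#' Bonferroni-adjusted over all pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment Multiplicity adjustment; only `"bonferroni"` is
#'   provided.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw` (two-sided normal) and `p_adjusted`.
#' @export
dunn_pairwise <- function(x, g = NULL, adjustment = c("bonferroni")) {
  adjustment <- match.arg(adjustment)
  groups <- .as_group_list(x, g)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, gi, mean)
  n_i <- lengths(groups)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(length(groups), 2)
  nm <- names(groups)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(var_base * (1 / n_i[i] + 1 / n_i[j]))
    z <- if (se > 0) (mean_ranks[i] - mean_ranks[j]) / se else 0
    data.frame(group1 = nm[i], group2 = nm[j], z = unname(z),
               stringsAsFactors = FALSE)
  }))
  out$p_raw <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H(%d) = %.3f, P = %.4g, N = %d\n",
              x$df, x$H, x$p, x$N))
  cat("  mean ranks:",
      paste(sprintf("%s = %.2f", names(x$mean_ranks), x$mean_ranks),
            collapse = ", "), "\n")
  invisible(x)
}

# Normalize (list) or (values, labels) input into a named list of groups.
.as_group_list <- function(x, g) {
  if (is.list(x)) {
    groups <- lapply(x, function(v) v[!is.na(v)])
    if (is.null(names(groups))) {
      names(groups) <- paste0("group", seq_along(groups))
    }
  } else {
    if (is.null(g)) stop("supply `g` when `x` is a vector", call. = FALSE)
    keep <- !is.na(x) & !is.na(g)
    groups <- split(x[keep], factor(g[keep]))
  }
  if (any(lengths(groups) < 1L)) stop("each group needs >= 1 value",
                                      call. = FALSE)
  groups
}
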