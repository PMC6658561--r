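# Type-III (drop-term) sums of squares under effect coding.  Returns per-term
# SS/df plus the full-model RSS; used by both the two-way and the split-plot
# decompositions.
.type3_ss <- function(y, data, formula) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) {
    stop("design is rank deficient (empty cell?)", call. = FALSE)
  }
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  rss <- function(Xm) sum(qr.resid(qr(Xm), y)^2)
  rss_full <- rss(X)
  ss <- vapply(seq_along(labels), function(t) {
    rss(X[, asgn != t, drop = FALSE]) - rss_full
  }, numeric(1))
  df <- vapply(seq_along(labels), function(t) sum(asgn == t), integer(1))
  list(terms = labels, ss = ss, df = df,
       rss = rss_full, df_res = length(y) - ncol(X))
}

#' Two-way ANOVA with variance-explained partitioning
#'
#' Type-III sums of squares under effect coding for two crossed two-level
#' factors (appropriate for unbalanced cells of 6-8 animals), with the
#' fraction of variance explained per term.  By default the classical
#' eta-squared (term SS over total SS) is reported; partial eta-squared is
#' available via `es = "partial_eta2"`.  Optional post-hoc simple-effect
#' Student t-tests are Bonferroni-corrected over the four cell comparisons
#' (significance at `alpha / 4`).
#'
#' @param values Numeric response vector.
#' @param a,b Two-level factors (prenatal group, adult trauma induction).
#' @param es Effect-size flavor: `"eta2"` (classical, default) or
#'   `"partial_eta2"`.
#' @param posthoc Run the four simple-effect pairwise t-tests.
#' @param alpha Family significance level for the post-hoc tests
#'   (default 0.05, applied as `alpha / 4` per comparison).
#' @return Object of class `two_way_anova`: `$table` (term, SS, df, F, p,
#'   `var_explained`, including the residual row) and `$posthoc`.
#' @export
two_way_anova <- function(values, a, b, es = c("eta2", "partial_eta2"),
                          posthoc = TRUE, alpha = 0.05) {
  es <- match.arg(es)
  keep <- stats::complete.cases(values, a, b)
  y <- values[keep]
  a <- droplevels(as.factor(a[keep]))
  b <- droplevels(as.factor(b[keep]))
  if (nlevels(a) != 2L || nlevels(b) != 2L) {
    stop("both factors must have exactly 2 levels", call. = FALSE)
  }
  if (any(table(a, b) == 0L)) {
    stop("empty design cell: interaction inestimable", call. = FALSE)
  }
  d <- data.frame(y = y, A = a, B = b)
  dec <- .type3_ss(y, d, ~ A * B)
  ss_total <- sum((y - mean(y))^2)
  ms_res <- dec$rss / dec$df_res
  F_stat <- (dec$ss / dec$df) / ms_res
  p <- stats::pf(F_stat, dec$df, dec$df_res, lower.tail = FALSE)
  ve <- if (es == "eta2") dec$ss / ss_total else dec$ss / (dec$ss + dec$rss)
  tab <- data.frame(
    term = c(dec$terms, "Residuals"),
    ss = c(dec$ss, dec$rss),
    df = c(dec$df, dec$df_res),
    F = c(F_stat, NA),
    p = c(p, NA),
    var_explained = c(ve, if (es == "eta2") dec$rss / ss_total else NA),
    stringsAsFactors = FALSE)
  ph <- if (posthoc) .simple_effect_ttests(y, a, b, alpha) else NULL
  structure(list(table = tab, posthoc = ph, es = es, alpha = alpha,
                 ss_total = ss_total),
            class = "two_way_anova")
}

# The four simple-effect comparisons of a 2x2 design: each level of one
# factor compared across the levels of the other, pooled-variance Student t.
.simple_effect_ttests <- function(y, a, b, alpha) {
  la <- levels(a); lb <- levels(b)
  cmp <- list(
    list(at = c("A", la[1]), of = "B"), list(at = c("A", la[2]), of = "B"),
    list(at = c("B", lb[1]), of = "A"), list(at = c("B", lb[2]), of = "A"))
  out <- do.call(rbind, lapply(cmp, function(cc) {
    if (cc$at[1] == "A") {
      sel <- a == cc$at[2]; f <- b[sel]
    } else {
      sel <- b == cc$at[2]; f <- a[sel]
    }
    ys <- y[sel]
    g1 <- ys[f == levels(f)[1]]; g2 <- ys[f == levels(f)[2]]
    tt <- tryCatch(stats::t.test(g1, g2, var.equal = TRUE),
                   error = function(e)       # degenerate (constant) cells
                     list(statistic = NA_real_, parameter = NA_real_,
                          p.value = NA_real_))
    data.frame(stratum = paste0(cc$at[1], " = ", cc$at[2]),
               comparison = paste(levels(f)[1], "vs", levels(f)[2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p < alpha / nrow(out)
  out
}

#' Split-plot three-way ANOVA with a repeated within-subject factor
#'
#' Mixed design with two between-subject two-level factors (prenatal group,
#' adult trauma induction) and one within-subject factor measured on every
#' subject (e.g. the four amygdalar transcripts GILZ/FKBP51/GR/CRF).
#' Between-subject terms are tested against the subject-within-group error;
#' the within factor and its interactions against the subject-by-within
#' residual.  Sums of squares are Type III under effect coding, so
#' unbalanced between-subject cells are handled.  No sphericity adjustment
#' is applied by default; `gg = TRUE` applies the Greenhouse-Geisser
#' epsilon to the within-term degrees of freedom.
#'
#' @param values Numeric response (one row per subject x within-level).
#' @param subject Subject identifier.
#' @param a,b Between-subject two-level factors (constant within subject).
#' @param within Within-subject factor (every subject must have every
#'   level; incomplete subjects are dropped with a warning).
#' @param gg Apply the Greenhouse-Geisser correction to within-term tests.
#' @return Object of class `split_plot_anova` with `$table` (term, SS, df,
#'   error stratum, F, p, `var_explained` as classical eta-squared) and
#'   `$epsilon` (Greenhouse-Geisser estimate, reported even when unused).
#' @export
mixed_three_way_anova <- function(values, subject, a, b, within, gg = FALSE) {
  d <- data.frame(y = values, s = as.factor(subject),
                  A = as.factor(a), B = as.factor(b),
                  W = as.factor(within))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$s <- droplevels(d$s); d$A <- droplevels(d$A)
  d$B <- droplevels(d$B); d$W <- droplevels(d$W)
  k <- nlevels(d$W)
  if (k < 2L) stop("within factor needs >= 2 levels", call. = FALSE)
  cnt <- table(d$s, d$W)
  complete <- rownames(cnt)[apply(cnt == 1L, 1, all)]
  if (length(complete) < nlevels(d$s)) {
    warning(sprintf("%d subject(s) missing within-levels: excluded",
                    nlevels(d$s) - length(complete)))
    d <- droplevels(d[d$s %in% complete, , drop = FALSE])
  }
  # between-subject design must be constant within subject
  per_subj <- unique(d[, c("s", "A", "B")])
  if (anyDuplicated(per_subj$s)) {
    stop("between-subject factors vary within a subject", call. = FALSE)
  }
  if (nlevels(d$A) != 2L || nlevels(d$B) != 2L) {
    stop("both between factors must have exactly 2 levels", call. = FALSE)
  }
  n_subj <- nlevels(d$s)
  if (any(table(per_subj$A, per_subj$B) == 0L)) {
    stop("empty between-subject cell", call. = FALSE)
  }

  # between stratum: Type III on subject means, rescaled by k
  m_s <- tapply(d$y, d$s, mean)[levels(d$s)]
  sd_between <- data.frame(m = as.numeric(m_s),
                           A = per_subj$A[match(levels(d$s), per_subj$s)],
                           B = per_subj$B[match(levels(d$s), per_subj$s)])
  dec_b <- .type3_ss(sd_between$m, sd_between, ~ A * B)
  ss_between <- k * dec_b$ss
  ss_subj_err <- k * dec_b$rss
  df_subj_err <- n_subj - 4L
  ms_subj_err <- ss_subj_err / df_subj_err

  # within stratum: Type III on the full fixed model; residual is the
  # subject-by-within remainder
  dec_f <- .type3_ss(d$y, d, ~ A * B * W)
  ss_swg <- dec_f$rss - ss_subj_err
  df_swg <- df_subj_err * (k - 1L)
  ms_swg <- ss_swg / df_swg
  within_terms <- c("W", "A:W", "B:W", "A:B:W")
  iw <- match(within_terms, dec_f$terms)

  eps <- .gg_epsilon(d)
  adj <- if (gg) eps else 1

  term <- c(dec_b$terms, "Subjects (error)", within_terms,
            "Subjects x Within (error)")
  ss <- c(ss_between, ss_subj_err, dec_f$ss[iw], ss_swg)
  df <- c(dec_b$df, df_subj_err, dec_f$df[iw], df_swg)
  F_stat <- c(ss_between / dec_b$df / ms_subj_err, NA,
              (dec_f$ss[iw] / dec_f$df[iw]) / ms_swg, NA)
  p <- c(stats::pf(F_stat[1:3], dec_b$df, df_subj_err, lower.tail = FALSE),
         NA,
         stats::pf(F_stat[5:8], adj * dec_f$df[iw], adj * df_swg,
                   lower.tail = FALSE),
         NA)
  ss_total <- sum((d$y - mean(d$y))^2)
  tab <- data.frame(
    term = term, ss = ss, df = df,
    stratum = c(rep("between", 4), rep("within", 5)),
    F = F_stat, p = p,
    var_explained = ss / ss_total,
    stringsAsFactors = FALSE)
  structure(list(table = tab, epsilon = eps, gg = gg, k = k,
                 n_subjects = n_subj, ss_total = ss_total),
            class = "split_plot_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-cell covariance of the
# k repeated measures.
.gg_epsilon <- function(d) {
  k <- nlevels(d$W)
  wide <- tapply(d$y, list(d$s, d$W), mean)
  cell <- interaction(d$A, d$B)[match(rownames(wide), d$s)]
  centered <- wide - apply(wide, 2, function(col) ave(col, cell))
  S <- crossprod(centered) / (nrow(wide) - nlevels(cell))
  mean_diag <- mean(diag(S)); mean_all <- mean(S)
  row_means <- rowMeans(S)
  num <- (k * (mean_diag - mean_all))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * mean_all^2)
  if (den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type III, effect coding)\n")
  tab <- x$table
  tab$var_explained <- sprintf("%.1f%%", 100 * tab$var_explained)
  print(format(tab, digits = 4), row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat(sprintf("Post-hoc simple effects (significance at alpha/4 = %.4f):\n",
                x$alpha / 4))
    print(format(x$posthoc, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.split_plot_anova <- function(x, ...) {
  cat(sprintf("Split-plot ANOVA: %d subjects x %d within-levels%s\n",
              x$n_subjects, x$k,
              if (x$gg) sprintf(" (Greenhouse-Geisser eps = %.3f)", x$epsilon)
              else ""))
  tab <- x$table
  tab$var_explained <- sprintf("%.1f%%", 100 * tab$var_explained)
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}
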