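# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (sort/enumerate/lm) so they share no code path with
# the implementation.

# Flag the boundary-inclusive extreme ceiling(q*n)-rank set of each test by
# sorting and value-membership (ties at the cutoff expand the set).
oracle_flags <- function(table, config) {
  sapply(config$tests, function(ts) {
    x <- table[[ts$column]]
    n <- sum(!is.na(x))
    k <- ceiling(config$percentile * n)
    xs <- sort(x)                       # drops NA
    extreme_values <- if (ts$direction == "low") xs[seq_len(k)]
                      else rev(xs)[seq_len(k)]
    out <- x %in% extreme_values
    out[is.na(x)] <- NA
    out
  })
}

# Two-way Type III SS via nested lm() fits under effect coding.
oracle_two_way_ss <- function(y, a, b) {
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  d <- data.frame(y = y, a = factor(a), b = factor(b))
  rss <- function(f) deviance(lm(f, data = d))
  full <- rss(y ~ a * b)
  X <- model.matrix(~ a * b, d)
  drop_col <- function(j) {
    sum(lsfit(X[, -j, drop = FALSE], y, intercept = FALSE)$residuals^2)
  }
  c(a = drop_col(2) - full, b = drop_col(3) - full,
    ab = drop_col(4) - full, residual = full)
}

# Split-plot SS for a *balanced* design by explicit marginal-mean formulas.
oracle_split_plot_ss <- function(y, subj, a, b, w) {
  d <- data.frame(y = y, s = factor(subj), a = factor(a), b = factor(b),
                  w = factor(w))
  k <- nlevels(d$w)
  mu <- mean(d$y)
  m <- function(...) ave(d$y, ..., FUN = mean)
  ma <- m(d$a); mb <- m(d$b); mw <- m(d$w)
  mab <- m(d$a, d$b); maw <- m(d$a, d$w); mbw <- m(d$b, d$w)
  mabw <- m(d$a, d$b, d$w)
  ms <- m(d$s)
  c(A = sum((ma - mu)^2),
    B = sum((mb - mu)^2),
    AB = sum((mab - ma - mb + mu)^2),
    subj_err = sum((ms - mab)^2),
    W = sum((mw - mu)^2),
    AW = sum((maw - ma - mw + mu)^2),
    BW = sum((mbw - mb - mw + mu)^2),
    ABW = sum((mabw - mab - maw - mbw + ma + mb + mw - mu)^2),
    swg = sum((y - mabw - ms + mab)^2))
}

# Naive IUPAC scanner: test every offset on the given strand's sequence.
IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_scan <- function(sequence, pattern, max_mm) {
  seqc <- strsplit(toupper(sequence), "")[[1]]
  patc <- strsplit(toupper(pattern), "")[[1]]
  L <- length(seqc); P <- length(patc)
  if (L < P) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(L - P + 1)) {
    mm <- 0
    for (j in seq_len(P)) {
      if (!seqc[i + j - 1] %in% IUPAC_ORACLE[[patc[j]]]) mm <- mm + 1
    }
    if (mm <= max_mm) starts <- c(starts, i)
  }
  starts
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Random DNA with no N.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Ct record builder for the molecular tests.
make_ct <- function(sample, gene, ct, group) {
  data.frame(sample = sample, gene = gene, ct = ct, group = group,
             stringsAsFactors = FALSE)
}
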