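#' Define one behavioral test of the battery
#'
#' A test specification names the measurement column and says in which
#' direction an "extreme" animal lies: `direction = "low"` flags the lowest
#' tail (e.g. risk-assessment time, startle latency, percent pre-pulse
#' inhibition), `direction = "high"` the upper tail (e.g. home-cage activity
#' in the non-active phase, percent of marbles buried).
#'
#' @param name Test identifier.
#' @param column Column of the animal table holding the metric; defaults to
#'   `name`.
#' @param direction `"low"` or `"high"`: which tail counts as extreme.
#' @return A `test_spec` object.
#' @export
test_spec <- function(name, column = name, direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(column), length(column) == 1L)
  structure(list(name = name, column = column, direction = direction),
            class = "test_spec")
}

#' Define the behavioral battery and classification rule
#'
#' The classifier flags animals lying in the extreme `percentile` tail of
#' each test (boundary inclusive) and labels an animal "PTSD-like" when it
#' is extreme in at least `min_extreme_tests` of the tests.
#'
#' @param tests List of [test_spec()] objects.
#' @param min_extreme_tests Minimum number of extreme tests for the
#'   PTSD-like label (default 3 of 5).
#' @param percentile Tail fraction defining "extreme" (default 0.20); must
#'   lie strictly between 0 and 0.5.
#' @param reference Optional logical or integer vector selecting the rows of
#'   the input table used as the cutoff reference population.  The default
#'   (`NULL`) uses every animal in the table, i.e. cutoffs are computed on
#'   the pooled trauma-exposed cohort.
#' @return A `battery_config` object.
#' @seealso [default_battery()], [compute_cutoffs()], [classify_battery()]
#' @export
battery_config <- function(tests, min_extreme_tests = 3L, percentile = 0.20,
                           reference = NULL) {
  if (inherits(tests, "test_spec")) tests <- list(tests)
  stopifnot(length(tests) >= 1L,
            all(vapply(tests, inherits, logical(1), "test_spec")))
  if (!(is.numeric(percentile) && length(percentile) == 1L &&
        percentile > 0 && percentile < 0.5)) {
    stop("`percentile` must lie strictly between 0 and 0.5", call. = FALSE)
  }
  min_extreme_tests <- as.integer(min_extreme_tests)
  if (min_extreme_tests < 1L || min_extreme_tests > length(tests)) {
    stop("`min_extreme_tests` must be between 1 and the number of tests",
         call. = FALSE)
  }
  names(tests) <- vapply(tests, `[[`, character(1), "name")
  structure(list(tests = tests, min_extreme_tests = min_extreme_tests,
                 percentile = percentile, reference = reference),
            class = "battery_config")
}

#' The five-test battery used for PTSD-like phenotyping
#'
#' Risk-assessment time (dark/light transfer), latency to peak startle
#' amplitude and percent pre-pulse inhibition are scored on their lower
#' tail; home-cage locomotion in the non-active phase and percent of
#' marbles buried on their upper tail.
#'
#' @inheritParams battery_config
#' @return A `battery_config` with the five standard tests.
#' @export
default_battery <- function(min_extreme_tests = 3L, percentile = 0.20,
                            reference = NULL) {
  battery_config(
    tests = list(
      test_spec("risk_assessment",   direction = "low"),
      test_spec("startle_latency",   direction = "low"),
      test_spec("ppi",               direction = "low"),
      test_spec("homecage_activity", direction = "high"),
      test_spec("marbles_buried",    direction = "high")
    ),
    min_extreme_tests = min_extreme_tests,
    percentile = percentile,
    reference = reference
  )
}

#' Compute per-test percentile cutoffs
#'
#' Cutoffs use the nearest-rank empirical quantile so that "the lowest 20%"
#' is a well-defined animal set: with `n` reference values and tail fraction
#' `q`, the low-direction cutoff is the `ceiling(q * n)`-th smallest value
#' and the high-direction cutoff the `ceiling(q * n)`-th largest.
#'
#' @param table Data frame with one row per animal.
#' @param config A [battery_config()].
#' @return A data frame of class `cutoff_set` with one row per test:
#'   `test`, `column`, `direction`, `cutoff`, `n_reference`.
#' @export
compute_cutoffs <- function(table, config) {
  stopifnot(is.data.frame(table), inherits(config, "battery_config"))
  ref <- config$reference
  ref_tab <- if (is.null(ref)) table else table[ref, , drop = FALSE]
  q <- config$percentile
  rows <- lapply(config$tests, function(ts) {
    if (!ts$column %in% names(table)) {
      stop("battery column not found in table: '", ts$column, "'",
           call. = FALSE)
    }
    x <- ref_tab[[ts$column]]
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      stop("test '", ts$name, "' has fewer than 2 non-missing reference ",
           "values", call. = FALSE)
    }
    n <- length(x)
    k <- ceiling(q * n)
    xs <- sort(x)
    cutoff <- if (ts$direction == "low") xs[k] else xs[n - k + 1L]
    data.frame(test = ts$name, column = ts$column, direction = ts$direction,
               cutoff = cutoff, n_reference = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("cutoff_set", "data.frame")
  out
}

#' Flag animals extreme on each test
#'
#' The boundary is inclusive: a value exactly at the cutoff is flagged
#' ("in the upper or lower boundary").  Missing values yield `NA` flags.
#'
#' @param table Data frame with one row per animal.
#' @param cutoffs A `cutoff_set` from [compute_cutoffs()].
#' @return Logical matrix, one row per animal, one column per test.
#' @export
flag_extremes <- function(table, cutoffs) {
  stopifnot(is.data.frame(table), inherits(cutoffs, "cutoff_set"))
  flags <- vapply(seq_len(nrow(cutoffs)), function(i) {
    x <- table[[cutoffs$column[i]]]
    if (cutoffs$direction[i] == "low") x <= cutoffs$cutoff[i]
    else x >= cutoffs$cutoff[i]
  }, logical(nrow(table)))
  flags <- matrix(flags, nrow = nrow(table),
                  dimnames = list(rownames(table), cutoffs$test))
  flags
}

#' Label animals PTSD-like from their extreme flags
#'
#' The extremity score is the number of tests on which an animal is
#' extreme; the label is "PTSD-like" when the score reaches
#' `min_extreme_tests`, otherwise "resilient".  Animals missing one or more
#' tests are excluded by default (`NA` label); with
#' `incomplete = "proportional"` the threshold is scaled to the observed
#' tests (`score / n_observed >= min_extreme_tests / n_tests`).
#'
#' @param flags Logical flag matrix from [flag_extremes()].
#' @param config The [battery_config()] used to produce the flags.
#' @param incomplete How to treat animals with missing tests: `"exclude"`
#'   (default) or `"proportional"`.
#' @return A data frame of class `classification_result`: the flags,
#'   `score`, `n_tests_observed` and `label` (factor, levels
#'   `resilient` / `PTSD-like`).
#' @export
classify_battery <- function(flags, config,
                             incomplete = c("exclude", "proportional")) {
  incomplete <- match.arg(incomplete)
  stopifnot(is.matrix(flags), is.logical(flags),
            inherits(config, "battery_config"))
  if (nrow(flags) == 0L) stop("no animals to classify", call. = FALSE)
  k <- config$min_extreme_tests
  n_tests <- length(config$tests)
  score <- rowSums(flags, na.rm = TRUE)
  n_obs <- rowSums(!is.na(flags))
  label <- ifelse(score >= k, "PTSD-like", "resilient")
  if (incomplete == "exclude") {
    label[n_obs < n_tests] <- NA
  } else {
    ok <- n_obs > 0L
    label[ok] <- ifelse(score[ok] / n_obs[ok] >= k / n_tests,
                        "PTSD-like", "resilient")
    label[!ok] <- NA
  }
  out <- data.frame(flags, score = as.integer(score),
                    n_tests_observed = as.integer(n_obs),
                    label = factor(label, levels = c("resilient", "PTSD-like")))
  class(out) <- c("classification_result", "data.frame")
  out
}

#' Classify a cohort in one step
#'
#' Convenience wrapper: cutoffs, flags and labels from a single animal
#' table.
#'
#' @inheritParams compute_cutoffs
#' @inheritParams classify_battery
#' @return List of class `battery_classification` with elements `cutoffs`,
#'   `flags` and `result`.
#' @export
classify_cohort <- function(table, config = default_battery(),
                            incomplete = c("exclude", "proportional")) {
  cutoffs <- compute_cutoffs(table, config)
  flags <- flag_extremes(table, cutoffs)
  result <- classify_battery(flags, config, incomplete = incomplete)
  structure(list(cutoffs = cutoffs, flags = flags, result = result,
                 config = config),
            class = "battery_classification")
}

#' Keep animals at or above a minimum extremity score
#'
#' Used for tissue-sampling inclusion (e.g. restricting molecular assays to
#' the most extreme animals).
#'
#' @param result A `classification_result`.
#' @param min_score Minimum extremity score to retain.
#' @return The filtered `classification_result`.
#' @export
filter_by_score <- function(result, min_score) {
  stopifnot(inherits(result, "classification_result"))
  result[result$score >= min_score, , drop = FALSE]
}

#' Cross-tabulate PTSD-like labels by group
#'
#' @param result A `classification_result` (or factor/character label
#'   vector with levels `resilient` / `PTSD-like`).
#' @param grouping Vector with exactly two levels identifying each
#'   animal's group.
#' @return A 2x2 integer matrix of class `contingency_2x2` (rows = groups,
#'   columns = `PTSD-like`, `resilient`).  Animals with `NA` label are
#'   dropped.
#' @export
prevalence_table <- function(result, grouping) {
  label <- if (inherits(result, "classification_result")) result$label
           else result
  label <- factor(label, levels = c("resilient", "PTSD-like"))
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) != 2L) {
    stop("`grouping` must have exactly 2 levels; stratify first for more",
         call. = FALSE)
  }
  grouping <- droplevels(grouping)
  keep <- !is.na(label)
  tab <- table(group = grouping[keep], label = label[keep])
  out <- cbind(`PTSD-like` = tab[, "PTSD-like"],
               resilient = tab[, "resilient"])
  storage.mode(out) <- "integer"
  class(out) <- c("contingency_2x2", class(out))
  out
}

#' Per-group prevalence of the PTSD-like label
#'
#' @param tab A `contingency_2x2` from [prevalence_table()].
#' @param percent Report percentages rounded to integers (as printed in
#'   study reports) instead of fractions.
#' @return Named numeric vector of per-group prevalences.
#' @export
prevalence <- function(tab, percent = FALSE) {
  stopifnot(inherits(tab, "contingency_2x2") ||
              (is.matrix(tab) && all(dim(tab) == 2L)))
  p <- tab[, 1] / rowSums(tab)
  if (percent) p <- round(100 * p)
  p
}

#' @export
print.battery_classification <- function(x, ...) {
  n <- nrow(x$result)
  n_ptsd <- sum(x$result$label == "PTSD-like", na.rm = TRUE)
  cat("Battery classification:", n, "animals,",
      length(x$config$tests), "tests\n")
  cat(sprintf("  extreme tail: %.0f%%; PTSD-like rule: >= %d tests\n",
              100 * x$config$percentile, x$config$min_extreme_tests))
  cat(sprintf("  PTSD-like: %d (%.1f%%); excluded (incomplete): %d\n",
              n_ptsd, 100 * n_ptsd / n, sum(is.na(x$result$label))))
  invisible(x)
}
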