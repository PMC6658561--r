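#' Configuration for an end-to-end pipeline run
#'
#' @param seed Integer master seed; every random stream of the run derives
#'   from it, so a config reproduces all numbers.
#' @param battery A [battery_config()] or path to a YAML battery file.
#' @param cohort A [cohort_params()] for the behavioral cohort, or a path
#'   to an animal-table CSV to load instead of simulating.
#' @param panel A [panel_params()] for the molecular panel.
#' @param n_panel_per_cell Animals per 2x2 design cell for the expression
#'   panel (default 7, within the 6-8 range typical of such assays).
#' @param alpha Significance level recorded in the report.
#' @param out_dir Optional directory; when given, every artifact is
#'   written there as CSV plus a run log.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, battery = default_battery(),
                       cohort = cohort_params(), panel = panel_params(),
                       n_panel_per_cell = 7L, alpha = 0.05,
                       out_dir = NULL) {
  if (is.character(battery)) battery <- read_battery_config(battery)
  stopifnot(inherits(battery, "battery_config"))
  if (!(is.numeric(seed) && length(seed) == 1L && seed == round(seed))) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), battery = battery,
                 cohort = cohort, panel = panel,
                 n_panel_per_cell = as.integer(n_panel_per_cell),
                 alpha = alpha, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a trauma-exposed behavioral cohort, classifies
#' PTSD-like animals, cross-tabulates labels by prenatal group with the
#' continuity-corrected chi-square and phi, simulates the 2x2 molecular
#' panel, runs the per-gene two-way ANOVA with variance explained, the
#' split-plot three-way ANOVA across transcripts, and the
#' methylation-expression correlation.  With `out_dir` set, writes every
#' table plus a run log carrying the seed and a config fingerprint.
#'
#' @param config A [run_config()].
#' @return List of class `battery_report` with elements `animals`,
#'   `classification`, `contingency`, `chi_square`, `prevalence`,
#'   `panel`, `anova_per_gene`, `anova_three_way`, `coupling`, `seed`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # behavioral cohort
  if (is.character(config$cohort)) {
    animals <- read_animal_table(config$cohort)
  } else {
    cp <- config$cohort
    cp$seed <- .substream_seed(seed, 101L)
    animals <- simulate_behavior_cohort(cp)
  }
  trauma <- if ("exposure" %in% names(animals)) {
    animals[animals$exposure == "trauma", , drop = FALSE]
  } else animals
  cls <- classify_cohort(trauma, config$battery)
  tab <- prevalence_table(cls$result, trauma$prenatal)
  chi <- yates_chi_square(tab)

  # molecular panel on a full 2x2 design
  m <- config$n_panel_per_cell
  design <- data.frame(
    animal_id = sprintf("p%03d", seq_len(4 * m)),
    prenatal = factor(rep(rep(c("control", "stressed"), each = m), 2),
                      levels = c("control", "stressed")),
    exposure = factor(rep(c("no_trauma", "trauma"), each = 2 * m),
                      levels = c("no_trauma", "trauma")))
  pp <- config$panel
  pp$seed <- .substream_seed(seed, 202L)
  panel <- simulate_expression_panel(design, pp)
  genes <- rownames(pp$cell_means)
  anova_per_gene <- lapply(genes, function(g) {
    two_way_anova(panel[[g]], panel$prenatal, panel$exposure,
                  alpha = config$alpha)
  })
  names(anova_per_gene) <- genes
  long <- panel_long(panel, genes)
  anova3 <- mixed_three_way_anova(long$expression, long$animal_id,
                                  long$prenatal, long$exposure, long$gene)
  coupling <- pearson_correlation(panel$percent_methylation,
                                  panel[[pp$meth_gene]])

  hash <- .fnv1a(c(seed, utils::capture.output(utils::str(config))))
  report <- structure(
    list(animals = animals, classification = cls, contingency = tab,
         chi_square = chi,
         prevalence = prevalence(tab),
         panel = panel, anova_per_gene = anova_per_gene,
         anova_three_way = anova3, coupling = coupling,
         seed = seed, config_hash = hash),
    class = "battery_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report bundle to a directory
#'
#' @param report A `battery_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "battery_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_animal_table(report$animals, fp("animals.csv"))
  utils::write.csv(cbind(animal_id = report$animals$animal_id[
                           match(rownames(report$classification$flags),
                                 rownames(report$animals))],
                         as.data.frame(report$classification$result)),
                   fp("classification.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$classification$cutoffs),
                   fp("cutoffs.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$contingency)),
                   fp("contingency.csv"))
  utils::write.csv(as.data.frame(report$panel), fp("panel.csv"),
                   row.names = FALSE)
  for (g in names(report$anova_per_gene)) {
    utils::write.csv(report$anova_per_gene[[g]]$table,
                     fp(sprintf("anova_%s.csv", g)), row.names = FALSE)
  }
  utils::write.csv(report$anova_three_way$table, fp("anova_three_way.csv"),
                   row.names = FALSE)
  log <- c(
    sprintf("seed: %d", report$seed),
    sprintf("config_hash: %s", report$config_hash),
    sprintf("chi_square_corrected: %.6f", report$chi_square$statistic_corrected),
    sprintf("phi: %.6f", report$chi_square$phi),
    sprintf("prevalence: %s",
            paste(sprintf("%s=%.4f", names(report$prevalence),
                          report$prevalence), collapse = ", ")),
    sprintf("coupling_r: %.4f (P = %.4g)", report$coupling$r,
            report$coupling$p))
  writeLines(log, fp("run_log.txt"))
  invisible(dir)
}

#' @export
print.battery_report <- function(x, ...) {
  cat("Stress-battery pipeline report (seed", x$seed,
      ", config", x$config_hash, ")\n\n")
  print(x$classification)
  cat("\nPTSD-like prevalence by prenatal group:\n")
  print(round(x$prevalence, 3))
  cat("\n")
  print(x$chi_square)
  cat("\nMethylation-expression coupling (panel): ")
  print(x$coupling)
  cat("\nPer-gene variance explained (prenatal / trauma / interaction):\n")
  for (g in names(x$anova_per_gene)) {
    ve <- x$anova_per_gene[[g]]$table$var_explained[1:3]
    cat(sprintf("  %-7s %5.1f%% %5.1f%% %5.1f%%\n", g,
                100 * ve[1], 100 * ve[2], 100 * ve[3]))
  }
  invisible(x)
}
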