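# Deterministic sub-seed for a named random stream, so that adding a new
# stream to a generator never perturbs draws of the existing streams.
.substream_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + stream * 1299721
  as.integer(s %% 2147483647)
}

.with_stream <- function(seed, stream, expr) {
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(.substream_seed(seed, stream))
  }
  expr
}

.CELLS <- c("control_no_trauma", "stressed_no_trauma",
            "control_trauma", "stressed_trauma")

#' Parameters of the synthetic behavioral cohort
#'
#' The generator draws, per animal, a latent susceptibility score (shared
#' across the five tests) shifted upward by `latent_effect` for prenatally
#' stressed animals; each observed metric is a direction-signed loading on
#' that latent plus independent Gaussian noise.  The shared factor is what
#' makes extremes co-occur across tests, lifting the PTSD-like prevalence
#' above the 5.8% independence null.  The defaults are calibrated so that
#' classifying the default cohort (35 control / 46 prenatally stressed
#' trauma-exposed males, pooled 20% cutoffs, 3-of-5 rule) yields long-run
#' prevalences near 8.6% and 26.1%.
#'
#' @param n_per_group Named integer vector of animals per design cell;
#'   names from `control_no_trauma`, `stressed_no_trauma`,
#'   `control_trauma`, `stressed_trauma`.  Defaults to the two
#'   trauma-exposed cells, 35 and 46.
#' @param latent_effect Latent-score shift for prenatally stressed
#'   animals (calibrated default 0.8).
#' @param test_loadings Length-5 loadings of the five battery metrics on
#'   the latent score.
#' @param noise_sd Per-test residual SD (recycled to 5).
#' @param target_prevalences Per-prenatal-group PTSD-like fractions the
#'   calibration aims at; carried along for calibration checks.
#' @param seed Optional integer seed (split into per-stream sub-seeds).
#' @return A `cohort_params` object.
#' @export
cohort_params <- function(n_per_group = c(control_trauma = 35L,
                                          stressed_trauma = 46L),
                          latent_effect = 0.8,
                          test_loadings = rep(1, 5),
                          noise_sd = 1,
                          target_prevalences = c(control = 3 / 35,
                                                 stressed = 12 / 46),
                          seed = NULL) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% .CELLS)) {
    stop("`n_per_group` must be named with design cells: ",
         paste(.CELLS, collapse = ", "), call. = FALSE)
  }
  if (any(n_per_group < 1) || any(n_per_group != round(n_per_group))) {
    stop("cell sizes must be positive integers", call. = FALSE)
  }
  noise_sd <- rep_len(noise_sd, 5L)
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0", call. = FALSE)
  if (length(test_loadings) != 5L) {
    stop("`test_loadings` must have length 5", call. = FALSE)
  }
  if (any(target_prevalences < 0 | target_prevalences > 1)) {
    stop("target prevalences must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, latent_effect = latent_effect,
                 test_loadings = test_loadings, noise_sd = noise_sd,
                 target_prevalences = target_prevalences, seed = seed),
            class = "cohort_params")
}

#' Simulate a behavioral cohort
#'
#' One row per animal with design labels (`prenatal`, `exposure`) and the
#' five battery metrics (`risk_assessment`, `startle_latency`, `ppi`,
#' `homecage_activity`, `marbles_buried`).  Low-direction tests load
#' negatively on the latent susceptibility score so that susceptible
#' animals fall in the low tail, high-direction tests positively.
#'
#' @param params A [cohort_params()] object.
#' @return Data frame of class `animal_table`.
#' @export
simulate_behavior_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n_cell <- params$n_per_group
  n <- sum(n_cell)
  cell <- rep(names(n_cell), n_cell)
  prenatal <- factor(ifelse(grepl("^stressed", cell), "stressed", "control"),
                     levels = c("control", "stressed"))
  exposure <- factor(ifelse(grepl("no_trauma$", cell), "no_trauma", "trauma"),
                     levels = c("no_trauma", "trauma"))
  latent <- .with_stream(params$seed, 1L, stats::rnorm(n)) +
    params$latent_effect * (prenatal == "stressed")
  # the three low-direction tests load negatively, the two high ones
  # positively (matching the default battery directions)
  dir_sign <- c(risk_assessment = -1, startle_latency = -1, ppi = -1,
                homecage_activity = 1, marbles_buried = 1)
  metrics <- lapply(seq_along(dir_sign), function(j) {
    noise <- .with_stream(params$seed, 1L + j,
                          stats::rnorm(n, sd = params$noise_sd[j]))
    dir_sign[j] * params$test_loadings[j] * latent + noise
  })
  names(metrics) <- names(dir_sign)
  out <- data.frame(animal_id = sprintf("a%03d", seq_len(n)),
                    prenatal = prenatal, exposure = exposure,
                    sex = "M", latent = latent, metrics,
                    stringsAsFactors = FALSE)
  class(out) <- c("animal_table", "data.frame")
  out
}

#' Parameters of the synthetic molecular panel
#'
#' @param gene_names Transcripts measured per animal (default the four
#'   amygdalar glucocorticoid-pathway markers).
#' @param cell_means Gene-by-cell matrix of mean relative expression
#'   (columns named by design cell).  The default emulates the reported
#'   effect pattern: GILZ reduced by both the prenatal stressor and adult
#'   trauma induction with no interaction; GR and CRF reduced, and FKBP51
#'   raised, mainly by trauma induction among prenatally stressed animals.
#' @param residual_sd Within-cell SD of relative expression.
#' @param meth_coupling_r Target Pearson correlation between percent CpG
#'   methylation and the coupled gene's expression (default -0.6).
#' @param meth_noise_sd SD of the independent component of the
#'   methylation latent; `NULL` (default) uses `sqrt(1 - r^2)` so the
#'   latent is standard normal.
#' @param meth_gene Gene whose expression the methylation couples to.
#' @param seed Optional integer seed.
#' @return A `panel_params` object.
#' @export
panel_params <- function(gene_names = c("GILZ", "FKBP51", "GR", "CRF"),
                         cell_means = NULL,
                         residual_sd = 0.18,
                         meth_coupling_r = -0.6,
                         meth_noise_sd = NULL,
                         meth_gene = "GILZ",
                         seed = NULL) {
  if (is.null(cell_means)) {
    cell_means <- rbind(
      GILZ   = c(1.00, 0.78, 0.75, 0.50),
      FKBP51 = c(1.00, 1.05, 1.02, 1.35),
      GR     = c(1.00, 1.02, 0.75, 0.62),
      CRF    = c(1.00, 1.08, 0.98, 0.72))
    colnames(cell_means) <- .CELLS
    cell_means <- cell_means[gene_names[gene_names %in% rownames(cell_means)],
                             , drop = FALSE]
  }
  stopifnot(is.matrix(cell_means),
            all(rownames(cell_means) %in% gene_names))
  if (residual_sd <= 0) stop("residual_sd must be > 0", call. = FALSE)
  if (abs(meth_coupling_r) > 1) stop("|meth_coupling_r| must be <= 1",
                                     call. = FALSE)
  if (!meth_gene %in% gene_names) stop("meth_gene not in gene_names",
                                       call. = FALSE)
  structure(list(gene_names = gene_names, cell_means = cell_means,
                 residual_sd = residual_sd,
                 meth_coupling_r = meth_coupling_r,
                 meth_noise_sd = meth_noise_sd, meth_gene = meth_gene,
                 seed = seed),
            class = "panel_params")
}

#' Simulate gene expression and coupled CpG methylation for a cohort
#'
#' Gene values are cell mean plus Gaussian noise.  Percent methylation is
#' built by a Gaussian copula on the standardized expression of the
#' coupled gene: a latent `r * z + sqrt(1 - r^2) * e` squashed through the
#' normal CDF onto (0, 1) and scaled to percent, so the beta constraint
#' holds by construction and the sample Pearson correlation tracks the
#' target `r` (mild attenuation from the squash, about 3%).
#'
#' @param design An `animal_table` (or data frame) with `prenatal` and
#'   `exposure` columns.
#' @param params A [panel_params()] object.
#' @return Data frame of class `molecular_panel`: design labels, one
#'   column per gene, and `percent_methylation` in `[0, 100]`.
#' @export
simulate_expression_panel <- function(design, params = panel_params()) {
  stopifnot(is.data.frame(design), inherits(params, "panel_params"),
            all(c("prenatal", "exposure") %in% names(design)))
  cell <- paste(as.character(design$prenatal),
                as.character(design$exposure), sep = "_")
  unknown <- setdiff(unique(cell), colnames(params$cell_means))
  if (length(unknown)) {
    stop("design cell(s) without specified means: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(design)
  genes <- rownames(params$cell_means)
  expr <- lapply(seq_along(genes), function(g) {
    noise <- .with_stream(params$seed, 10L + g,
                          stats::rnorm(n, sd = params$residual_sd))
    params$cell_means[genes[g], cell] + noise
  })
  names(expr) <- genes

  r <- params$meth_coupling_r
  s <- if (is.null(params$meth_noise_sd)) sqrt(1 - r^2)
       else params$meth_noise_sd
  zg <- as.numeric(scale(expr[[params$meth_gene]]))
  if (any(is.na(zg))) zg <- rep(0, n)  # degenerate zero-variance gene
  eps <- .with_stream(params$seed, 30L, stats::rnorm(n))
  latent <- r * zg + s * eps
  percent_methylation <- 100 * stats::pnorm(latent)

  out <- data.frame(animal_id = if ("animal_id" %in% names(design))
                      design$animal_id else sprintf("a%03d", seq_len(n)),
                    prenatal = design$prenatal, exposure = design$exposure,
                    expr, percent_methylation = percent_methylation,
                    stringsAsFactors = FALSE)
  class(out) <- c("molecular_panel", "data.frame")
  out
}

#' Reshape a molecular panel to long format
#'
#' One row per animal-by-gene measurement, ready for the split-plot ANOVA
#' ([mixed_three_way_anova()]).
#'
#' @param panel A `molecular_panel`.
#' @param genes Gene columns to stack (default: all present from the
#'   panel's gene set).
#' @return Data frame with `animal_id`, `prenatal`, `exposure`, `gene`,
#'   `expression`.
#' @export
panel_long <- function(panel, genes = NULL) {
  stopifnot(is.data.frame(panel))
  if (is.null(genes)) {
    genes <- setdiff(names(panel),
                     c("animal_id", "prenatal", "exposure", "sex",
                       "percent_methylation"))
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    data.frame(animal_id = panel$animal_id, prenatal = panel$prenatal,
               exposure = panel$exposure, gene = g,
               expression = panel[[g]], stringsAsFactors = FALSE)
  }))
  out$gene <- factor(out$gene, levels = genes)
  out
}

#' Simulate a knockdown experiment
#'
#' Knockdown-virus animals receive per-side stained infection areas
#' (log-normal, spanning the 1-5 rubric) and a PTSD-like behavior score
#' rising with total infection score at `score_slope`; control-virus
#' animals are infected but their score stays at baseline, since the
#' scrambled construct does not silence the target.  A binary label marks
#' scores of 3 or more as PTSD-like.
#'
#' @param n_kd,n_cv Animals per virus group (defaults 9 knockdown, 10
#'   control virus).
#' @param score_slope Behavior-score increase per unit total infection
#'   score in the knockdown group (default 0.45).
#' @param noise_sd SD of the behavior-score noise (default 0.9).
#' @param baseline_cv,baseline_kd Score intercepts (defaults 1.5, 0.3).
#' @param seed Optional integer seed.
#' @return Data frame of class `kd_table`: `animal_id`, `group` (CV/KD),
#'   per-side areas and scores, `total`, `ptsd_score`, `label`.
#' @export
simulate_kd_experiment <- function(n_kd = 9L, n_cv = 10L, score_slope = 0.45,
                                   noise_sd = 0.9, baseline_cv = 1.5,
                                   baseline_kd = 0.3, seed = NULL) {
  n_kd <- as.integer(n_kd); n_cv <- as.integer(n_cv)
  if (n_kd < 1L || n_cv < 1L) stop("group sizes must be >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  n <- n_kd + n_cv
  areas <- .with_stream(seed, 1L,
                        matrix(stats::rlnorm(2 * n, meanlog = log(18),
                                             sdlog = 0.8), ncol = 2))
  sc <- infection_score(areas[, 1], areas[, 2])
  group <- factor(rep(c("CV", "KD"), c(n_cv, n_kd)), levels = c("CV", "KD"))
  noise <- .with_stream(seed, 2L, stats::rnorm(n, sd = noise_sd))
  ptsd_score <- ifelse(group == "KD",
                       baseline_kd + score_slope * sc$total,
                       baseline_cv) + noise
  out <- data.frame(animal_id = sprintf("kd%02d", seq_len(n)),
                    group = group, sc, ptsd_score = ptsd_score,
                    label = factor(ifelse(ptsd_score >= 3, "PTSD-like",
                                          "resilient"),
                                   levels = c("resilient", "PTSD-like")),
                    stringsAsFactors = FALSE)
  class(out) <- c("kd_table", "data.frame")
  out
}

#' Parameters of the synthetic human candidate-gene table
#'
#' Emulates a trauma-exposed civilian cohort: a lifetime trauma-event
#' count (TEI), a blood expression value with sex-specific TEI slopes, a
#' CpG methylation beta coupled to expression in males only (via a clamped
#' logistic construction, so betas always lie in `(0, 1)`), and standard
#' nuisance covariates.
#'
#' @param n_subjects Cohort size (default 435: 135 male, 300 female).
#' @param sex_ratio Fraction male (default 135/435).
#' @param tei_distribution Function of `n` returning non-negative integer
#'   trauma-event counts (default Poisson with mean 4).
#' @param expr_tei_slope_male,expr_tei_slope_female Expression change per
#'   traumatic event (defaults -0.12 and 0: the male-only association).
#' @param meth_expr_slope_male Methylation-latent change per expression
#'   unit in males (default -0.5; females are uncoupled).
#' @param meth_noise_sd SD of the methylation latent noise (default 0.5).
#' @param covariate_spec Named list of functions of `n` generating the
#'   nuisance covariates (defaults: age, ancestry, substance use,
#'   treatment).
#' @param seed Optional integer seed.
#' @return A `human_table_params` object.
#' @export
human_table_params <- function(n_subjects = 435L,
                               sex_ratio = 135 / 435,
                               tei_distribution = function(n)
                                 stats::rpois(n, lambda = 4),
                               expr_tei_slope_male = -0.12,
                               expr_tei_slope_female = 0,
                               meth_expr_slope_male = -0.5,
                               meth_noise_sd = 0.5,
                               covariate_spec = list(
                                 age = function(n)
                                   round(pmax(18, stats::rnorm(n, 40, 12))),
                                 ancestry = function(n)
                                   sample(c("AA", "EA"), n, replace = TRUE,
                                          prob = c(0.9, 0.1)),
                                 substance_use = function(n)
                                   stats::rbinom(n, 1, 0.3),
                                 treatment = function(n)
                                   stats::rbinom(n, 1, 0.25)),
                               seed = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < length(covariate_spec) + 2L) {
    stop("n_subjects must exceed the covariate count by at least 2",
         call. = FALSE)
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]",
                                           call. = FALSE)
  stopifnot(is.function(tei_distribution),
            all(vapply(covariate_spec, is.function, logical(1))))
  structure(list(n_subjects = n_subjects, sex_ratio = sex_ratio,
                 tei_distribution = tei_distribution,
                 expr_tei_slope_male = expr_tei_slope_male,
                 expr_tei_slope_female = expr_tei_slope_female,
                 meth_expr_slope_male = meth_expr_slope_male,
                 meth_noise_sd = meth_noise_sd,
                 covariate_spec = covariate_spec, seed = seed),
            class = "human_table_params")
}

#' Simulate the human candidate-gene subject table
#'
#' @param params A [human_table_params()] object.
#' @return Data frame of class `human_table`: `subject_id`, `sex`
#'   (`male`/`female`), `tei`, `expression`, `meth_beta` in `(0, 1)`, and
#'   the configured covariates.
#' @export
simulate_human_table <- function(params = human_table_params()) {
  stopifnot(inherits(params, "human_table_params"))
  n <- params$n_subjects
  n_male <- round(params$sex_ratio * n)
  sex <- factor(rep(c("male", "female"), c(n_male, n - n_male)),
                levels = c("male", "female"))
  tei <- .with_stream(params$seed, 1L, params$tei_distribution(n))
  if (length(tei) != n || any(tei < 0) || any(tei != round(tei))) {
    stop("tei_distribution must return n non-negative integer counts",
         call. = FALSE)
  }
  slope <- ifelse(sex == "male", params$expr_tei_slope_male,
                  params$expr_tei_slope_female)
  expression <- slope * tei +
    .with_stream(params$seed, 2L, stats::rnorm(n))
  expr_c <- expression - mean(expression)
  eta <- stats::qlogis(0.25) +
    ifelse(sex == "male", params$meth_expr_slope_male, 0) * expr_c +
    .with_stream(params$seed, 3L,
                 stats::rnorm(n, sd = params$meth_noise_sd))
  meth_beta <- stats::plogis(eta)
  covs <- lapply(seq_along(params$covariate_spec), function(i) {
    .with_stream(params$seed, 10L + i, params$covariate_spec[[i]](n))
  })
  names(covs) <- names(params$covariate_spec)
  out <- data.frame(subject_id = sprintf("s%04d", seq_len(n)),
                    sex = sex, tei = tei, expression = expression,
                    meth_beta = meth_beta, covs, stringsAsFactors = FALSE)
  class(out) <- c("human_table", "data.frame")
  out
}
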