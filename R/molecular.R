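#' Relative expression by the 2^-ddCt method
#'
#' Standard relative quantification of real-time PCR: per sample,
#' `dCt = Ct(target) - Ct(reference)`; `ddCt` is taken against the mean
#' `dCt` of the calibrator group; the fold change is `2^-ddCt`.  Technical
#' replicates of the same sample/gene are averaged first.
#'
#' @param ct Data frame of Ct records with columns `sample`, `gene`, `ct`
#'   and a group column.
#' @param target,reference Gene identifiers of the target and the
#'   reference (housekeeping) gene.
#' @param calibrator_group Level of `group_col` whose mean dCt anchors the
#'   fold change at 1.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return Data frame with one row per sample: `sample`, `group`,
#'   `delta_ct`, `ddct`, `fold`.
#' @export
relative_expression_ddct <- function(ct, target, reference, calibrator_group,
                                     group_col = "group") {
  stopifnot(is.data.frame(ct),
            all(c("sample", "gene", "ct", group_col) %in% names(ct)))
  if (any(ct$ct <= 0, na.rm = TRUE)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  grp <- unique(ct[, c("sample", group_col)])
  if (anyDuplicated(grp$sample)) {
    stop("a sample appears in more than one group", call. = FALSE)
  }
  tgt <- mean_ct[mean_ct$gene == target, c("sample", "ct")]
  ref <- mean_ct[mean_ct$gene == reference, c("sample", "ct")]
  if (nrow(ref) == 0L) stop("reference gene '", reference, "' not found",
                            call. = FALSE)
  if (nrow(tgt) == 0L) stop("target gene '", target, "' not found",
                            call. = FALSE)
  d <- merge(tgt, ref, by = "sample", suffixes = c("_target", "_reference"))
  missing_ref <- setdiff(tgt$sample, ref$sample)
  if (length(missing_ref)) {
    stop("samples missing reference Ct: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  d$delta_ct <- d$ct_target - d$ct_reference
  d <- merge(d, grp, by = "sample")
  cal <- d$delta_ct[d[[group_col]] == calibrator_group]
  if (length(cal) == 0L) {
    stop("calibrator group '", calibrator_group, "' absent", call. = FALSE)
  }
  d$ddct <- d$delta_ct - mean(cal)
  d$fold <- 2^(-d$ddct)
  d[, c("sample", group_col, "delta_ct", "ddct", "fold")]
}

#' Knockdown efficiency under two reference normalizations
#'
#' Quantifies shRNA knockdown of a target transcript twice: against a
#' housekeeping gene (overall downregulation in the sample) and against
#' the viral reporter (downregulation per infected unit, correcting for
#' infection efficiency).  Fold changes are relative to the control-virus
#' group.  Samples lacking a reporter Ct (uninfected) are flagged and
#' excluded from the reporter normalization.
#'
#' @param ct Ct records as in [relative_expression_ddct()], with the
#'   target, housekeeping and reporter genes measured per sample.
#' @param target Target gene (default `"GILZ"`).
#' @param housekeeping Housekeeping reference (default `"HPRT"`).
#' @param reporter Viral reporter (default `"GFP"`).
#' @param control_group Control-virus group level.
#' @param group_col Name of the grouping column.
#' @return List of class `kd_report`: `$vs_housekeeping` and
#'   `$vs_reporter` (per-sample fold tables), `$excluded` (samples without
#'   reporter Ct) and `$summary` (per-group geometric-mean folds).
#' @export
kd_efficiency <- function(ct, target = "GILZ", housekeeping = "HPRT",
                          reporter = "GFP", control_group,
                          group_col = "group") {
  stopifnot(is.data.frame(ct))
  if (!any(ct[[group_col]] == control_group)) {
    stop("control group '", control_group, "' absent", call. = FALSE)
  }
  vs_hk <- relative_expression_ddct(ct, target, housekeeping,
                                    calibrator_group = control_group,
                                    group_col = group_col)
  has_rep <- unique(ct$sample[ct$gene == reporter & !is.na(ct$ct)])
  excluded <- setdiff(unique(ct$sample), has_rep)
  ct_rep <- ct[ct$sample %in% has_rep, , drop = FALSE]
  vs_rep <- relative_expression_ddct(ct_rep, target, reporter,
                                     calibrator_group = control_group,
                                     group_col = group_col)
  summarize <- function(d) {
    s <- stats::aggregate(fold ~ d[[group_col]], data = d,
                          FUN = function(f) exp(mean(log(f))))
    names(s) <- c("group", "geomean_fold")
    s
  }
  structure(list(vs_housekeeping = vs_hk, vs_reporter = vs_rep,
                 excluded = excluded,
                 summary = list(vs_housekeeping = summarize(vs_hk),
                                vs_reporter = summarize(vs_rep))),
            class = "kd_report")
}

#' @export
print.kd_report <- function(x, ...) {
  cat("Knockdown efficiency (fold vs control virus)\n")
  cat("  normalized to housekeeping gene:\n")
  print(format(x$summary$vs_housekeeping, digits = 3), row.names = FALSE)
  cat("  normalized to viral reporter:\n")
  print(format(x$summary$vs_reporter, digits = 3), row.names = FALSE)
  if (length(x$excluded)) {
    cat("  excluded (no reporter Ct):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score the degree of viral infection from stained areas
#'
#' Rubric used for histological confirmation of bilateral amygdala
#' injections: each side's GFP-stained area (mm^2) maps to an integer
#' score 1-5 via half-open bins `[0,5) = 1`, `[5,10) = 2`, `[10,25) = 3`,
#' `[25,50) = 4`, `[50,Inf) = 5` (an area of exactly 50 mm^2 scores 5);
#' the total is the sum of the two sides.
#'
#' @param left_area_mm2,right_area_mm2 Non-negative per-side stained
#'   areas; vectorized.
#' @return Data frame of class `infection_score`: per-side areas and
#'   scores plus `total`.
#' @export
infection_score <- function(left_area_mm2, right_area_mm2) {
  stopifnot(length(left_area_mm2) == length(right_area_mm2))
  if (any(c(left_area_mm2, right_area_mm2) < 0, na.rm = TRUE)) {
    stop("infection areas must be non-negative", call. = FALSE)
  }
  side_score <- function(a) findInterval(a, c(0, 5, 10, 25, 50))
  ls <- side_score(left_area_mm2)
  rs <- side_score(right_area_mm2)
  out <- data.frame(left_area_mm2 = left_area_mm2,
                    right_area_mm2 = right_area_mm2,
                    left_score = as.integer(ls),
                    right_score = as.integer(rs),
                    total = as.integer(ls + rs))
  class(out) <- c("infection_score", "data.frame")
  out
}

#' Methylation-expression coupling report
#'
#' Joins per-sample percent CpG methylation with relative expression and
#' reports their Pearson correlation (e.g. GRE-site methylation against
#' GILZ fold change), together with the paired scatter table.
#'
#' @param meth Data frame with columns `sample` and `percent_methylation`.
#' @param expr Data frame with columns `sample` and `fold` (as returned by
#'   [relative_expression_ddct()]).
#' @return List of class `coupling_report`: `$correlation`
#'   (a `correlation_result`) and `$data` (paired table).
#' @export
methylation_expression_report <- function(meth, expr) {
  stopifnot(is.data.frame(meth), is.data.frame(expr),
            all(c("sample", "percent_methylation") %in% names(meth)),
            all(c("sample", "fold") %in% names(expr)))
  d <- merge(meth[, c("sample", "percent_methylation")],
             expr[, c("sample", "fold")], by = "sample")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("no overlapping sample ids", call. = FALSE)
  if (nrow(d) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  structure(list(
    correlation = pearson_correlation(d$percent_methylation, d$fold),
    data = d), class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("Methylation-expression coupling:\n  ")
  print(x$correlation)
  invisible(x)
}
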