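#' Read a per-animal table from CSV
#'
#' Expects one row per animal with an `animal_id` column; design columns
#' (`prenatal`, `exposure`) are coerced to factors when present.  Unknown
#' columns are preserved.
#'
#' @param path CSV file.
#' @return Data frame of class `animal_table`.
#' @export
read_animal_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty animal table: ", path, call. = FALSE)
  if (!"animal_id" %in% names(tab)) {
    stop("missing required column 'animal_id' in ", path, call. = FALSE)
  }
  dup <- tab$animal_id[duplicated(tab$animal_id)]
  if (length(dup)) {
    stop("duplicate animal ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if ("prenatal" %in% names(tab)) {
    tab$prenatal <- factor(tab$prenatal,
                           levels = c("control", "stressed"))
  }
  if ("exposure" %in% names(tab)) {
    tab$exposure <- factor(tab$exposure,
                           levels = c("no_trauma", "trauma"))
  }
  class(tab) <- c("animal_table", "data.frame")
  tab
}

#' Write a per-animal table to CSV
#'
#' @param table Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_animal_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a battery configuration from a YAML file
#'
#' Expected layout (a top-level `battery:` block is also accepted):
#' ```yaml
#' percentile: 0.20
#' min_extreme_tests: 3
#' tests:
#'   - name: risk_assessment
#'     direction: low
#'   - name: marbles_buried
#'     direction: high
#' ```
#'
#' @param path YAML file.
#' @return A [battery_config()] object.
#' @export
read_battery_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$battery)) cfg <- cfg$battery
  if (is.null(cfg$tests)) stop("config lacks a `tests` list", call. = FALSE)
  tests <- lapply(cfg$tests, function(ts) {
    if (is.null(ts$name)) stop("test entry without `name`", call. = FALSE)
    test_spec(ts$name,
              column = if (is.null(ts$column)) ts$name else ts$column,
              direction = if (is.null(ts$direction)) "low" else ts$direction)
  })
  battery_config(
    tests = tests,
    min_extreme_tests = if (is.null(cfg$min_extreme_tests)) 3L
                        else cfg$min_extreme_tests,
    percentile = if (is.null(cfg$percentile)) 0.20 else cfg$percentile)
}

# Tiny FNV-1a hash of a character vector; used only to fingerprint run
# configurations in logs.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte; multiply in 16-bit halves to stay
    # within exact double-precision integer range
    lo <- h %% 65536; hi <- h %/% 65536
    lo <- bitwXor(lo, b)
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
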