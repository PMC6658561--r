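# IUPAC code -> set of matching bases (used for mismatch counting and by
# the brute-force test oracle via the exported helper below).
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Define a consensus motif model
#'
#' IUPAC consensus with a mismatch budget, defaulting to the palindromic
#' glucocorticoid response element half-sites with a 3-bp spacer,
#' `RGNACANNNTGTNCY`.  An `N` in the *scanned sequence* never counts as a
#' match, whatever the pattern allows at that position.
#'
#' @param pattern IUPAC consensus string.
#' @param max_mismatches Mismatch budget (default 1); must be smaller than
#'   the pattern length.
#' @param strands Which strands to scan: `"both"` (default), `"+"` or
#'   `"-"`.
#' @return A `motif_model` object.
#' @export
gre_motif <- function(pattern = "RGNACANNNTGTNCY", max_mismatches = 1L,
                      strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("empty pattern", call. = FALSE)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(.IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC code(s): ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L || max_mismatches >= nchar(pattern)) {
    stop("max_mismatches must be in [0, pattern length)", call. = FALSE)
  }
  structure(list(pattern = pattern, max_mismatches = max_mismatches,
                 strands = strands),
            class = "motif_model")
}

# Count mismatches of a subject substring against an IUPAC pattern;
# subject N (or any non-ACGT letter) always counts as a mismatch.
.iupac_mismatches <- function(pattern_chars, subject_chars) {
  sum(!mapply(function(p, s) s %in% .IUPAC_SETS[[p]],
              pattern_chars, subject_chars))
}

#' Scan a promoter sequence for motif hits
#'
#' Finds every position (on the configured strands) where the IUPAC
#' consensus matches with at most the allowed number of mismatches.
#' Matching is case-insensitive; `N` bases in the sequence never match.
#' Coordinates are 1-based inclusive on the forward strand for both
#' strands; minus-strand hits are reported at their forward-strand
#' footprint.
#'
#' @param sequence Character scalar or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.
#' @param model A [gre_motif()] model.
#' @param seqname Sequence name recorded in the output.
#' @return Data frame of class `gre_hits`: `seqname`, `start`, `end`,
#'   `strand`, `mismatches`, `match` (forward-strand substring) and
#'   `contains_cpg` (whether that substring contains the `CG`
#'   dinucleotide).
#' @export
scan_gre <- function(sequence, model = gre_motif(), seqname = "seq") {
  stopifnot(inherits(model, "motif_model"))
  seq_chr <- toupper(as.character(sequence))
  if (length(seq_chr) != 1L) stop("one sequence at a time", call. = FALSE)
  if (nzchar(seq_chr) && grepl("[^ACGTN]", seq_chr)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  L <- nchar(seq_chr)
  plen <- nchar(model$pattern)
  empty <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), match = character(),
                      contains_cpg = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("gre_hits", "data.frame")
  if (L < plen) return(empty)

  subj <- Biostrings::DNAString(seq_chr)
  pat <- Biostrings::DNAString(model$pattern)
  scan_one <- function(subject, strand) {
    m <- Biostrings::matchPattern(pat, subject,
                                  max.mismatch = model$max_mismatches,
                                  fixed = "subject")
    if (length(m) == 0L) return(NULL)
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    if (strand == "-") {
      fs <- L - en + 1L; fe <- L - st + 1L
    } else {
      fs <- st; fe <- en
    }
    data.frame(start = fs, end = fe, strand = strand,
               scanned = substring(as.character(subject), st, en),
               stringsAsFactors = FALSE)
  }
  parts <- list()
  if (model$strands %in% c("both", "+")) parts$fwd <- scan_one(subj, "+")
  if (model$strands %in% c("both", "-")) {
    parts$rev <- scan_one(Biostrings::reverseComplement(subj), "-")
  }
  hits <- do.call(rbind, parts)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)

  # recount mismatches explicitly so sequence N is always a mismatch,
  # independent of the matcher's ambiguity semantics
  pchars <- strsplit(model$pattern, "")[[1]]
  hits$mismatches <- vapply(hits$scanned, function(s) {
    .iupac_mismatches(pchars, strsplit(s, "")[[1]])
  }, integer(1), USE.NAMES = FALSE)
  hits <- hits[hits$mismatches <= model$max_mismatches, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)

  fwd_sub <- substring(seq_chr, hits$start, hits$end)
  out <- data.frame(seqname = seqname, start = hits$start, end = hits$end,
                    strand = hits$strand, mismatches = hits$mismatches,
                    match = fwd_sub,
                    contains_cpg = grepl("CG", fwd_sub, fixed = TRUE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gre_hits", "data.frame")
  out
}

#' Retain only CpG-containing hits
#'
#' Keeps the hits whose forward-strand footprint contains the `CG`
#' dinucleotide -- the candidate pyrosequencing targets, since only a CpG
#' can carry the methylation mark.  Coordinates are untouched.
#'
#' @param hits A `gre_hits` data frame from [scan_gre()].
#' @return The CpG-containing subset, same class and columns.
#' @export
filter_cpg_hits <- function(hits) {
  stopifnot(inherits(hits, "gre_hits"))
  out <- hits[hits$contains_cpg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert hit coordinates to TSS-relative positions
#'
#' Promoter-style signed coordinates: the base immediately upstream of the
#' transcription start site is -1, the TSS base itself is +1, and there is
#' no position 0.  A hit spanning sequence positions 1..22 with the TSS at
#' 2093 maps to -2092..-2071.
#'
#' @param hits A `gre_hits` data frame.
#' @param tss_position 1-based position of the TSS in the scanned
#'   sequence (may be one base past the end for a purely upstream
#'   fragment).
#' @return `hits` with added columns `tss_start` and `tss_end` (signed,
#'   `tss_start <= tss_end`).
#' @export
to_tss_coordinates <- function(hits, tss_position) {
  stopifnot(inherits(hits, "gre_hits"),
            is.numeric(tss_position), length(tss_position) == 1L)
  map <- function(i) ifelse(i < tss_position,
                            -(tss_position - i),
                            i - tss_position + 1L)
  hits$tss_start <- as.integer(map(hits$start))
  hits$tss_end <- as.integer(map(hits$end))
  hits
}

#' Read a promoter sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used (a message is emitted
#'   if there are several).
#' @return Named character scalar (name = FASTA header word).
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (length(ss) > 1L) message("using first of ", length(ss), " sequences")
  stats::setNames(as.character(ss[[1]]), names(ss)[1])
}

#' Write hits as a BED-like tab-separated table
#'
#' Columns: seqname, start, end, strand, mismatches, contains_cpg and (if
#' present) tss_start/tss_end.
#'
#' @param hits A `gre_hits` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gre_table <- function(hits, path) {
  stopifnot(inherits(hits, "gre_hits"))
  cols <- intersect(c("seqname", "start", "end", "strand", "mismatches",
                      "contains_cpg", "tss_start", "tss_end"), names(hits))
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
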