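#' Basepair-level scoring parameters
#'
#' Penalties are magnitudes: a length-L gap costs `gap_open + gap_extend * L`.
#' In bisulfite mode a read T aligned to a reference C scores (and counts in
#' NM) as a match, reflecting unmethylated-C conversion.
#'
#' @param match Reward for a matching basepair.
#' @param mismatch Penalty for a mismatching basepair.
#' @param gap_open Penalty for opening a gap.
#' @param gap_extend Penalty per gap basepair.
#' @param bisulfite Score read-T/reference-C as a match.
#' @return A list of class `bp_scoring_params`.
#' @export
bp_scoring_params <- function(match = 1, mismatch = 2, gap_open = 2,
                              gap_extend = 1, bisulfite = FALSE) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, bisulfite = isTRUE(bisulfite)),
            class = "bp_scoring_params")
}

#' Skeleton (affine bound) score of a k-mer run
#'
#' A fast affine estimate of the basepair alignment score a run could
#' achieve: `match * (read positions covered by the union of the run's
#' k-mer spans) - gap_open * (number of diagonal shifts) - gap_extend *
#' (total absolute diagonal change)`.  Used as the second candidate filter
#' before banded dynamic programming.
#'
#' @param run A `kmer_run` (or a data frame of chained matches).
#' @param pattern A `gapped_pattern` or 0/1 string.
#' @param params A `bp_scoring_params`.
#' @return The skeleton score (0 for an empty run).
#' @export
skeleton_score <- function(run, pattern, params = bp_scoring_params()) {
  pattern <- gapped_pattern(pattern)
  matches <- if (inherits(run, "kmer_run")) run$matches else run
  if (is.null(matches) || nrow(matches) == 0L) return(0)
  pm_skeleton(as.integer(matches$read_offset),
              as.integer(matches$window_offset), pattern$span,
              params$match, params$gap_open, params$gap_extend)
}

#' Banded affine-gap local alignment
#'
#' Smith-Waterman-style local alignment restricted to matrix cells whose
#' diagonal (reference index minus read index, 0-based) lies within
#' `band`.  Unaligned read ends are soft-clipped (`S` in the CIGAR).
#'
#' @param read,ref_segment Nucleotide strings.
#' @param band Integer vector `c(lo, hi)`: the admissible diagonal range.
#' @param params A `bp_scoring_params` (its `bisulfite` flag selects the
#'   asymmetric T/C match rule).
#' @return A list of class `bp_alignment`: `score`, `cigar` (S/M/I/D,
#'   consuming the whole read), 0-based half-open `read_start`/`read_end`
#'   and `ref_start`/`ref_end`, `nm` (edit distance), and `aligned`
#'   (FALSE when no cell scored positive).
#' @examples
#' banded_align("ACGTACGTAC", "ACGTACGTAC", c(-10, 10))$cigar  # "10M"
#' @export
banded_align <- function(read, ref_segment, band, params = bp_scoring_params()) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  read <- toupper(read)
  ref_segment <- toupper(ref_segment)
  a <- pm_banded_align(read, ref_segment, as.integer(band[1]),
                       as.integer(band[2]), params$match, params$mismatch,
                       params$gap_open, params$gap_extend, params$bisulfite)
  n <- nchar(read)
  cigar <- a$cigar
  if (nzchar(cigar)) {
    if (a$read_start > 0) cigar <- paste0(a$read_start, "S", cigar)
    if (a$read_end < n) cigar <- paste0(cigar, n - a$read_end, "S")
  }
  structure(list(score = a$score, cigar = cigar,
                 read_start = a$read_start, read_end = a$read_end,
                 ref_start = a$ref_start, ref_end = a$ref_end, nm = a$nm,
                 aligned = a$score > 0),
            class = "bp_alignment")
}

#' @export
print.bp_alignment <- function(x, ...) {
  cat(sprintf("alignment: score %g, cigar %s, ref [%d, %d), NM %d\n",
              x$score, if (nzchar(x$cigar)) x$cigar else "*",
              x$ref_start, x$ref_end, x$nm))
  invisible(x)
}

#' Re-score an alignment path
#'
#' Recomputes the affine-gap score of a reported alignment from its CIGAR,
#' the oriented read sequence and the reference.  Soft clips contribute
#' nothing.  Used to assert that every reported mapping score equals the
#' score of its own path.
#'
#' @param seq Oriented read sequence (as emitted in SAM SEQ).
#' @param refseq Reference sequence the mapping points into.
#' @param pos 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string with S/M/I/D operations.
#' @param params A `bp_scoring_params`.
#' @return The re-scored alignment score.
#' @export
rescore_alignment <- function(seq, refseq, pos, cigar, params = bp_scoring_params()) {
  ops <- parse_cigar(cigar)
  q <- 0L
  r <- as.integer(pos)
  score <- 0
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    op <- ops$op[i]
    if (op == "S") {
      q <- q + len
    } else if (op == "M") {
      rd <- strsplit(substr(seq, q + 1L, q + len), "")[[1]]
      rf <- strsplit(substr(refseq, r + 1L, r + len), "")[[1]]
      is_match <- rd == rf | (params$bisulfite & rd == "T" & rf == "C")
      score <- score + sum(ifelse(is_match, params$match, -params$mismatch))
      q <- q + len
      r <- r + len
    } else if (op == "I") {
      score <- score - params$gap_open - params$gap_extend * len
      q <- q + len
    } else if (op == "D") {
      score <- score - params$gap_open - params$gap_extend * len
      r <- r + len
    } else stop("unsupported CIGAR op: ", op)
  }
  score
}

#' Parse a CIGAR string into operations
#'
#' @param cigar A CIGAR string (`*` yields an empty table).
#' @return Data frame with columns `len` (integer) and `op` (character).
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar))
    return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(strsplit(cigar, "[MIDSHNPX=]")[[1]])
  ops <- strsplit(gsub("[0-9]", "", cigar), "")[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

#' CIGAR consumption lengths
#'
#' @param cigar A CIGAR string.
#' @return Named numeric vector with `read` (S/M/I) and `ref` (M/D)
#'   consumed lengths.
#' @export
cigar_lengths <- function(cigar) {
  ops <- parse_cigar(cigar)
  c(read = sum(ops$len[ops$op %in% c("S", "M", "I")]),
    ref = sum(ops$len[ops$op %in% c("M", "D")]))
}
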