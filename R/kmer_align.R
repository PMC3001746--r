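#' K-mer-level scoring parameters
#'
#' @param m Reward per matching sampled base.
#' @param g Penalty per indel base between chained k-mers.
#' @param max_diagonal_drift Maximum |change of diagonal| tolerated within
#'   one run (bp); echoes chaining across a small number of neighbouring
#'   diagonals.
#' @return A list of class `kmer_scoring_params`.
#' @export
kmer_scoring_params <- function(m = 1, g = 2, max_diagonal_drift = 10L) {
  stopifnot(m > 0, g >= 0, max_diagonal_drift >= 0)
  structure(list(m = m, g = g,
                 max_diagonal_drift = as.integer(max_diagonal_drift)),
            class = "kmer_scoring_params")
}

#' Greedy k-mer-level alignment of matches into collinear runs
#'
#' Matches between one read and one genomic window are processed in
#' (read_offset, window_offset) order.  A match extends a run when it is
#' strictly collinear with the run's last k-mer in both coordinates and its
#' diagonal drifts by at most `max_diagonal_drift`; the extension adds
#' `(t - ovl(d)) * m - g * gap` where `d` is the basepair overlap between
#' the two pattern placements and `gap` the diagonal change.  Among all
#' live runs the best-scoring extension is taken; a non-extending match
#' starts a new run scored `t * m`.  The best run is returned (ties go to
#' the smallest window offset).
#'
#' @param matches Data frame with integer columns `read_offset` and
#'   `window_offset` (0-based bp).
#' @param pattern A `gapped_pattern` or 0/1 string.
#' @param params A `kmer_scoring_params`.
#' @return A list of class `kmer_run`: `score`, and the chained `matches`
#'   (data frame, in chain order); a `score` of 0 with no matches for an
#'   empty input.
#' @examples
#' m <- data.frame(read_offset = c(0L, 2L), window_offset = c(5L, 7L))
#' kmer_align(m, "111", kmer_scoring_params(m = 1, g = 1))$score  # 5
#' @export
kmer_align <- function(matches, pattern, params = kmer_scoring_params()) {
  pattern <- gapped_pattern(pattern)
  if (is.null(matches) || nrow(matches) == 0L) {
    return(structure(list(score = 0,
                          matches = data.frame(read_offset = integer(0),
                                               window_offset = integer(0))),
                     class = "kmer_run"))
  }
  ovl <- overlap_table(pattern)
  res <- pm_kmer_align(as.integer(matches$read_offset),
                       as.integer(matches$window_offset),
                       as.integer(ovl), pattern$weight, pattern$span,
                       params$m, params$g, params$max_diagonal_drift)
  structure(list(score = res$score,
                 matches = data.frame(read_offset = res$read_offsets,
                                      window_offset = res$window_offsets)),
            class = "kmer_run")
}

#' @export
print.kmer_run <- function(x, ...) {
  cat(sprintf("k-mer run: score %g, %d chained matches\n",
              x$score, nrow(x$matches)))
  invisible(x)
}
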