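#' Build a multi-positional hash table over a batch of reads
#'
#' Each read is sampled with the gapped pattern at offsets `0, G, 2G, ...`
#' plus the terminal offset `length - span` (so both read ends are always
#' covered), and every usable k-mer contributes one entry `(read, offset)`
#' per key.  In bisulfite mode each sampled k-mer is stored under every key
#' obtained by converting its Ts to either C or T (k-mers with more than
#' `expansion_cap` Ts contribute nothing).  After insertion the
#' highest-frequency `1 - kept_fraction` of distinct keys becomes
#' discardable, with two safeguards that keep the filter a pure speed
#' knob aimed at repetitive k-mers: a frequency class is never split
#' (keys tied with the boundary frequency all survive), and a key is only
#' ever discarded when genuinely overrepresented — its entry count must
#' exceed both twice the mean entries-per-key and an absolute floor of
#' 10.  On near-uniform frequency distributions (no repeats) the filter
#' therefore removes nothing, which is what a sensitivity-first mapper
#' wants.
#'
#' @param reads Character vector of read sequences (uppercased internally).
#' @param pattern A `gapped_pattern` or 0/1 string.
#' @param offset_gap G, the gap between k-mer sampling offsets (bp).
#' @param bisulfite Expand read k-mer Ts into \{C, T\}.
#' @param include_rc Also index the reverse complement of every read
#'   (entries flagged `rc`); used by the ordinary mapping mode.
#' @param kept_fraction Fraction of distinct k-mer keys to retain.
#' @param expansion_cap Maximum number of Ts expanded per k-mer.
#' @return An object of class `mp_hash_index`.
#' @examples
#' idx <- build_read_index(c("ACGTACGTACGT"), "1011", offset_gap = 4)
#' index_lookup(idx, sample_kmer("ACGTACGTACGT", 0, "1011"))
#' @export
build_read_index <- function(reads, pattern, offset_gap = 1L,
                             bisulfite = FALSE, include_rc = FALSE,
                             kept_fraction = 1.0, expansion_cap = 10L) {
  pattern <- gapped_pattern(pattern)
  stopifnot(offset_gap >= 1L, kept_fraction > 0, kept_fraction <= 1)
  reads <- toupper(as.character(reads))
  ptr <- pm_build_index(reads, pattern$offsets, pattern$span,
                        as.integer(offset_gap), bisulfite, include_rc,
                        kept_fraction, as.integer(expansion_cap))
  structure(list(ptr = ptr, pattern = pattern,
                 offset_gap = as.integer(offset_gap), bisulfite = bisulfite,
                 include_rc = include_rc, kept_fraction = kept_fraction,
                 n_reads = length(reads)),
            class = "mp_hash_index")
}

#' Look up a k-mer key in a read index
#'
#' Pure retrieval: returns the entries recorded for `key`, or an empty
#' data frame when the key was never inserted or fell in the discarded
#' high-frequency set.
#'
#' @param index An `mp_hash_index`.
#' @param key A k-mer key string of length equal to the pattern weight.
#' @return A data frame with columns `read_id` (1-based), `offset`
#'   (0-based) and `rc`.
#' @export
index_lookup <- function(index, key) {
  stopifnot(inherits(index, "mp_hash_index"))
  if (is.null(key)) {
    return(data.frame(read_id = integer(0), offset = integer(0),
                      rc = logical(0)))
  }
  pm_index_lookup(index$ptr, toupper(key))
}

#' Summary statistics of a read index
#'
#' @param index An `mp_hash_index`.
#' @return A list with `n_entries`, `n_keys`, the retained `key` strings
#'   with their entry `count`, and the per-read `unmappable` flags (reads
#'   shorter than the pattern span).
#' @export
index_info <- function(index) {
  stopifnot(inherits(index, "mp_hash_index"))
  pm_index_info(index$ptr)
}

#' @export
print.mp_hash_index <- function(x, ...) {
  info <- index_info(x)
  cat(sprintf(
    "multi-positional hash index: %d reads, %g keys, %g entries%s\n",
    x$n_reads, info$n_keys, info$n_entries,
    if (x$bisulfite) " (bisulfite)" else ""))
  invisible(x)
}

#' Bisulfite k-mer-space expansion
#'
#' Every T in a bisulfite read may stand for a converted unmethylated C, so
#' a sampled k-mer is expanded into all strings obtained by independently
#' replacing each T with C or T (`2^#T` keys).
#'
#' @param kmer A string over ACGT.
#' @param expansion_cap Skip k-mers with more than this many Ts (returns
#'   an empty vector).
#' @return Character vector of expanded keys, sorted.
#' @examples
#' expand_bisulfite_kmers("TTA")  # TCA TTA CCA CTA (in sorted order)
#' @export
expand_bisulfite_kmers <- function(kmer, expansion_cap = 10L) {
  pm_expand_bisulfite(toupper(kmer), as.integer(expansion_cap))
}
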