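#' Parse a gapped sampling pattern
#'
#' A gapped pattern (spaced seed) is written as a 0/1 string: `1` marks a
#' sampled position, `0` a skipped one.  The *span* is the total length of
#' the string and the *weight* `t` the number of sampled positions.  A
#' k-mer match under pattern `P` requires equality only at the sampled
#' positions.
#'
#' @param text A non-empty string over `0`/`1` whose first and last
#'   characters are `1`.
#' @return An object of class `gapped_pattern` with fields `offsets`
#'   (0-based sampled positions), `span`, `weight` and `text`.
#' @examples
#' p <- gapped_pattern("11011")
#' p$offsets  # 0 1 3 4
#' @export
gapped_pattern <- function(text) {
  if (inherits(text, "gapped_pattern")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("pattern must be a single non-empty 0/1 string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("0", "1"))
  if (length(bad))
    stop(sprintf("pattern contains non-binary character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  if (chars[1] != "1")
    stop("pattern must start with '1' (leading '0' at position 1)")
  if (chars[length(chars)] != "1")
    stop(sprintf("pattern must end with '1' (trailing '0' at position %d)",
                 length(chars)))
  offsets <- which(chars == "1") - 1L
  structure(list(offsets = offsets, span = length(chars),
                 weight = length(offsets), text = text),
            class = "gapped_pattern")
}

#' @export
print.gapped_pattern <- function(x, ...) {
  cat(sprintf("gapped pattern %s (span %d, weight %d)\n",
              x$text, x$span, x$weight))
  invisible(x)
}

#' Default sampling patterns
#'
#' The built-in defaults: span-18/weight-11 for ordinary mapping and
#' span-18/weight-12 for bisulfite mapping.  Both can be overridden by any
#' user-supplied 0/1 string.  (A trailing unsampled position participates
#' in no match, so patterns are required to end on a sampled base.)
#'
#' @param bisulfite Return the bisulfite default instead of the mapping one.
#' @return A `gapped_pattern`.
#' @export
default_pattern <- function(bisulfite = FALSE) {
  gapped_pattern(if (bisulfite) "111010110100110111" else "111011011000110101")
}

#' Sample a gapped k-mer from a sequence
#'
#' Concatenates the bases at the pattern's sampled offsets starting at
#' `pos`.  Returns `NULL` when the pattern does not fit at `pos` or a
#' sampled base is not in `ACGT` (positions holding `N` at a sampled offset
#' void the k-mer; non-sampled positions are ignored).
#'
#' @param seq Uppercase nucleotide string.
#' @param pos 0-based start position.
#' @param pattern A `gapped_pattern` or 0/1 string.
#' @return The k-mer key string, or `NULL`.
#' @export
sample_kmer <- function(seq, pos, pattern) {
  pattern <- gapped_pattern(pattern)
  pm_sample_kmer(seq, as.integer(pos), pattern$offsets, pattern$span)
}

#' Pattern self-overlap function ovl(d)
#'
#' For two placements of the same pattern overlapping by `d` basepairs
#' (start shift `span - d`), `ovl(d)` is the number of sampled positions
#' they share.  It discounts the reward of chained overlapping k-mer
#' matches so that no sampled basepair is rewarded twice.
#'
#' @param pattern A `gapped_pattern` or 0/1 string.
#' @return An integer vector of length `span + 1`, named `"0" ... "span"`,
#'   with `ovl(0) = 0` and `ovl(span) = weight`.
#' @export
overlap_table <- function(pattern) {
  pattern <- gapped_pattern(pattern)
  mask <- integer(pattern$span)
  mask[pattern$offsets + 1L] <- 1L
  # correlate the mask with itself at start shift s = span - d
  ovl <- vapply(0:pattern$span, function(d) {
    s <- pattern$span - d
    if (s >= pattern$span) return(0L)
    sum(mask[seq_len(pattern$span - s) + s] * mask[seq_len(pattern$span - s)])
  }, integer(1))
  names(ovl) <- as.character(0:pattern$span)
  ovl
}
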