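#' Remove monoclonal (duplicate) reads
#'
#' Reads sharing an identical (reference, 5' start, strand) are presumed
#' PCR clones of one molecule; exactly one is retained — the highest DP
#' score, then first-seen.  The 5' coordinate of a reverse-strand mapping
#' is its rightmost reference position.
#'
#' @param mappings Mappings data frame (needs `ref`, `pos`, `strand`,
#'   `cigar`; `score` optional).
#' @return The deduplicated data frame, in original row order.
#' @export
remove_monoclonal <- function(mappings) {
  if (is.null(mappings) || nrow(mappings) == 0L) return(mappings)
  ref_len <- vapply(mappings$cigar, function(cg) cigar_lengths(cg)[["ref"]],
                    numeric(1), USE.NAMES = FALSE)
  five_prime <- ifelse(mappings$strand == "+", mappings$pos,
                       mappings$pos + ref_len - 1)
  key <- paste(mappings$ref, five_prime, mappings$strand, sep = "\r")
  score <- if (!is.null(mappings$score)) mappings$score else rep(0, nrow(mappings))
  ord <- order(-score, seq_len(nrow(mappings)))
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  out <- mappings[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call per-cytosine methylation from bisulfite mappings
#'
#' Walks every mapping's CIGAR against the reference.  At each reference
#' cytosine on the mapped strand (a forward C for `+` mappings, a forward
#' G — i.e. a reverse-strand C — for `-` mappings) a read C is methylated
#' evidence and a read T unmethylated evidence (G/A respectively on the
#' reverse strand, since SEQ is stored forward-oriented); any other base
#' is ignored.  Sites with informative coverage of at least
#' `min_coverage` are emitted with their trinucleotide context.
#'
#' @param mappings Bisulfite-mode mappings data frame (`ref`, `pos`,
#'   `strand`, `cigar`, `seq`).
#' @param genome Named character vector of reference sequences.
#' @param min_coverage Minimum informative reads for a call (default 5).
#' @return Data frame with `ref`, `pos` (0-based C position on the forward
#'   strand), `strand`, `context` (CpG/CHG/CHH), `meth`, `total`, `level`.
#' @export
call_methylation <- function(mappings, genome, min_coverage = 5L) {
  genome <- toupper(genome)
  counts <- new.env(parent = emptyenv())
  bump <- function(ref, pos, strand, is_meth) {
    k <- paste(ref, pos, strand, sep = "\r")
    v <- counts[[k]]
    if (is.null(v)) v <- c(0L, 0L)
    v[1L] <- v[1L] + as.integer(is_meth)
    v[2L] <- v[2L] + 1L
    counts[[k]] <- v
  }
  for (i in seq_len(nrow(mappings))) {
    ref <- mappings$ref[i]
    if (!ref %in% names(genome))
      stop("mapping references unknown sequence: ", ref)
    refseq <- genome[[ref]]
    ops <- parse_cigar(mappings$cigar[i])
    q <- 0L
    r <- as.integer(mappings$pos[i])
    strand <- mappings$strand[i]
    seq <- mappings$seq[i]
    for (k in seq_len(nrow(ops))) {
      len <- ops$len[k]
      op <- ops$op[k]
      if (op == "S" || op == "I") {
        q <- q + len
      } else if (op == "D") {
        r <- r + len
      } else if (op == "M") {
        if (r + len > nchar(refseq))
          stop("mapping runs past the end of ", ref)
        rf <- strsplit(substr(refseq, r + 1L, r + len), "")[[1]]
        rd <- strsplit(substr(seq, q + 1L, q + len), "")[[1]]
        if (strand == "+") {
          at <- which(rf == "C")
          for (j in at) {
            if (rd[j] == "C") bump(ref, r + j - 1L, "+", TRUE)
            else if (rd[j] == "T") bump(ref, r + j - 1L, "+", FALSE)
          }
        } else {
          at <- which(rf == "G")
          for (j in at) {
            if (rd[j] == "G") bump(ref, r + j - 1L, "-", TRUE)
            else if (rd[j] == "A") bump(ref, r + j - 1L, "-", FALSE)
          }
        }
        q <- q + len
        r <- r + len
      } else stop("unsupported CIGAR op: ", op)
    }
  }
  keys <- ls(counts)
  if (!length(keys))
    return(data.frame(ref = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      meth = integer(0), total = integer(0),
                      level = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(ref = vapply(parts, `[`, character(1), 1),
                    pos = as.integer(vapply(parts, `[`, character(1), 2)),
                    strand = vapply(parts, `[`, character(1), 3),
                    meth = vapply(keys, function(k) counts[[k]][1L],
                                  integer(1), USE.NAMES = FALSE),
                    total = vapply(keys, function(k) counts[[k]][2L],
                                   integer(1), USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[out$total >= min_coverage, , drop = FALSE]
  if (nrow(out)) {
    out$context <- vapply(seq_len(nrow(out)), function(i) {
      methyl_context(genome[[out$ref[i]]], out$pos[i], out$strand[i])
    }, character(1))
    out$level <- out$meth / out$total
    out <- out[order(out$ref, out$pos, out$strand), , drop = FALSE]
  } else {
    out$context <- character(0)
    out$level <- numeric(0)
  }
  rownames(out) <- NULL
  out[, c("ref", "pos", "strand", "context", "meth", "total", "level")]
}

# trinucleotide context of a cytosine at 0-based `pos` on `strand`
methyl_context <- function(refseq, pos, strand) {
  n <- nchar(refseq)
  at <- function(p) if (p >= 0 && p < n) substr(refseq, p + 1L, p + 1L) else ""
  if (strand == "+") {
    if (at(pos + 1L) == "G") "CpG"
    else if (at(pos + 2L) == "G") "CHG"
    else "CHH"
  } else {
    if (at(pos - 1L) == "C") "CpG"
    else if (at(pos - 2L) == "C") "CHG"
    else "CHH"
  }
}

#' Write a methylation map as tab-separated text
#'
#' @param calls Data frame from [call_methylation()].
#' @param path Output path.
#' @export
write_methylation <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Agreement-ratio contingency analysis
#'
#' For two samples compared at cytosine sites stratified by genotype class
#' (C/C homozygous vs C/nonC heterozygous) and by region (inside vs
#' outside a set of regions of interest, e.g. known imprinted genes), the
#' agreement ratio of a stratum is
#' `(no-difference fraction among C/nonC sites) /
#'  (no-difference fraction among C/C sites)`.
#' Random allele placement at heterozygous differentially methylated sites
#' depresses the ratio inside imprinted regions relative to the rest of
#' the genome.  Significance is assessed by a chi-square test on the 2x2
#' table (region) x (agreement at C/nonC sites), with Yates correction
#' when any expected count is below 5.
#'
#' @param inside,outside Numeric vectors of four non-negative counts:
#'   `c(cc_diff, cc_nodiff, cnonc_diff, cnonc_nodiff)` for sites inside
#'   and outside the regions.
#' @return A list of class `agreement_result`: `ratio_inside`,
#'   `ratio_outside`, `chi_square`, `p_value`, `table`.
#' @examples
#' agreement_ratio(c(7808, 5286, 7, 4), c(25170688, 16275243, 20963, 23299))
#' @export
agreement_ratio <- function(inside, outside) {
  stopifnot(length(inside) == 4L, length(outside) == 4L,
            all(inside >= 0), all(outside >= 0))
  one_ratio <- function(x, label) {
    cc <- x[1] + x[2]
    cn <- x[3] + x[4]
    if (cc == 0) stop("zero denominator: no C/C sites ", label)
    if (cn == 0) stop("zero denominator: no C/nonC sites ", label)
    if (x[2] == 0) stop("zero denominator: no C/C agreement ", label)
    (x[4] / cn) / (x[2] / cc)
  }
  ri <- one_ratio(inside, "inside the regions")
  ro <- one_ratio(outside, "outside the regions")
  tab <- rbind(inside = inside[3:4], outside = outside[3:4])
  colnames(tab) <- c("difference", "no_difference")
  expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
  test <- suppressWarnings(chisq.test(tab, correct = any(expected < 5)))
  structure(list(ratio_inside = ri, ratio_outside = ro,
                 chi_square = unname(test$statistic),
                 p_value = unname(test$p.value), table = tab),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "agreement ratio inside %.3f, outside %.3f (chi-square %.2f, p %.3g)\n",
    x$ratio_inside, x$ratio_outside, x$chi_square, x$p_value))
  invisible(x)
}
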