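#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences (ACGTN alphabet).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Mapper configuration
#'
#' Collects every tunable of the mapping pipeline.  `preset` (high, medium,
#' low, fast) sets the k-mer sampling gap `G` and the kept fraction of
#' distinct k-mers from the read length; any explicitly supplied value wins
#' over the preset.
#'
#' @param pattern Gapped pattern (0/1 string or `gapped_pattern`); defaults
#'   to the mode-appropriate built-in pattern.
#' @param offset_gap G, gap between k-mer sampling offsets in the reads (bp).
#' @param window_half_length W; genomic windows of length 2W slide with
#'   stride W (50% overlap) so any alignment of length at most W is fully
#'   contained in at least one window.
#' @param kept_fraction Fraction of lowest-frequency distinct k-mer keys
#'   retained in the index.
#' @param candidate_fraction Run and skeleton scores must exceed this
#'   fraction of the per-read running best to proceed (the 3/4 filters).
#' @param final_score_margin Candidates within this DP-score distance of
#'   the per-read best are kept by [select_best()].
#' @param kmer_params A [kmer_scoring_params()].
#' @param bp_params A [bp_scoring_params()].
#' @param band_pad Extra diagonals allowed on each side of a run's diagonal
#'   extent during banded alignment (bp).
#' @param bisulfite Bisulfite mapping mode.
#' @param expansion_cap Maximum Ts expanded per k-mer in bisulfite mode.
#' @param preset One of `"high"`, `"medium"`, `"low"`, `"fast"`, or `NULL`.
#' @param read_length Typical read length, used by the preset to scale `G`.
#' @return A list of class `mapper_config`.
#' @export
mapper_config <- function(pattern = NULL, offset_gap = NULL,
                          window_half_length = NULL, kept_fraction = NULL,
                          candidate_fraction = 0.75, final_score_margin = 0,
                          kmer_params = kmer_scoring_params(),
                          bp_params = NULL, band_pad = 10L,
                          bisulfite = FALSE, expansion_cap = 10L,
                          preset = NULL, read_length = 100L) {
  if (!is.null(preset)) {
    pp <- preset_params(preset, read_length)
    if (is.null(offset_gap)) offset_gap <- pp$offset_gap
    if (is.null(kept_fraction)) kept_fraction <- pp$kept_fraction
  }
  if (is.null(offset_gap)) offset_gap <- max(1L, ceiling(read_length / 12))
  if (is.null(kept_fraction)) kept_fraction <- 0.99
  if (is.null(pattern)) pattern <- default_pattern(bisulfite)
  pattern <- gapped_pattern(pattern)
  if (is.null(bp_params)) bp_params <- bp_scoring_params(bisulfite = bisulfite)
  if (bisulfite) bp_params$bisulfite <- TRUE
  if (is.null(window_half_length))
    window_half_length <- max(read_length, 500L)
  stopifnot(candidate_fraction > 0, candidate_fraction <= 1,
            final_score_margin >= 0, window_half_length >= read_length)
  structure(list(pattern = pattern, offset_gap = as.integer(offset_gap),
                 window_half_length = as.integer(window_half_length),
                 kept_fraction = kept_fraction,
                 candidate_fraction = candidate_fraction,
                 final_score_margin = final_score_margin,
                 kmer_params = kmer_params, bp_params = bp_params,
                 band_pad = as.integer(band_pad), bisulfite = bisulfite,
                 expansion_cap = as.integer(expansion_cap),
                 preset = if (is.null(preset)) NA_character_ else preset),
            class = "mapper_config")
}

#' Sensitivity presets
#'
#' The built-in speed/sensitivity trade-offs.  All presets but `fast` keep
#' 99% of the lowest-frequency distinct k-mers; `fast` discards the top 7%
#' highest-frequency k-mers (keeps 93%).  The k-mer sampling gap G scales
#' with read length: high `ceiling(L/16)`, medium `ceiling(L/12)`, low and
#' fast `ceiling(L/8)`.
#'
#' @param name One of `"high"`, `"medium"`, `"low"`, `"fast"`.
#' @param read_length Read length used to scale G.
#' @return List with `offset_gap` and `kept_fraction`.
#' @export
preset_params <- function(name, read_length = 100L) {
  name <- match.arg(name, c("high", "medium", "low", "fast"))
  div <- switch(name, high = 16, medium = 12, low = 8, fast = 8)
  list(offset_gap = max(1L, as.integer(ceiling(read_length / div))),
       kept_fraction = if (name == "fast") 0.93 else 0.99)
}

#' Enumerate sliding genome windows
#'
#' Windows of length 2W start at 0, W, 2W, ... (stride W, 50% overlap);
#' the final windows are truncated at the sequence end.  Windows never
#' span a sequence boundary.
#'
#' @param genome Named character vector of reference sequences.
#' @param W Window half-length (bp).
#' @return Data frame with columns `ref`, `start` (0-based) and `seq`.
#' @export
stream_windows <- function(genome, W) {
  W <- as.integer(W)
  stopifnot(W >= 1L)
  if (is.null(names(genome)) && length(genome))
    names(genome) <- paste0("seq", seq_along(genome))
  out <- lapply(names(genome), function(nm) {
    len <- nchar(genome[[nm]])
    if (len == 0L) return(NULL)
    starts <- if (len <= 2L * W) 0L else seq.int(0L, len - 1L, by = W)
    data.frame(ref = nm, start = starts,
               seq = substring(genome[[nm]], starts + 1L,
                               pmin(starts + 2L * W, len)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(ref = character(0), start = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  out
}

#' Map reads against a reference genome
#'
#' The full pipeline: the reads are indexed in a multi-positional hash
#' table (forward and reverse complement in ordinary mode; T-expanded
#' forward only in bisulfite mode, where instead both strands of every
#' reference sequence are streamed).  Each genomic window is sampled at
#' every position; matches are grouped per read and chained by
#' [kmer_align()]; runs passing the running-best k-mer filter are scored
#' with [skeleton_score()]; runs passing the skeleton filter go through
#' banded DP.  Candidates are deduplicated across overlapping windows on
#' (reference, position, strand) and resolved per read by [select_best()].
#'
#' @param reads Character vector of read sequences; names become read ids
#'   (default `read1 ...`).
#' @param genome Named character vector of reference sequences.
#' @param config A [mapper_config()].
#' @return A list of class `map_result`:
#'   `mappings` (final per-read mappings with `unique`/`mapq` flags),
#'   `candidates` (the deduplicated candidate buffer), `unmapped`
#'   (read names without any candidate), `reads`, `genome`, `config`.
#' @export
map_reads <- function(reads, genome, config = mapper_config()) {
  stopifnot(inherits(config, "mapper_config"))
  reads <- vapply(reads, toupper, character(1))
  if (is.null(names(reads)) && length(reads))
    names(reads) <- paste0("read", seq_along(reads))
  genome <- vapply(genome, toupper, character(1))
  if (is.null(names(genome)) && length(genome))
    names(genome) <- paste0("seq", seq_along(genome))
  pat <- config$pattern
  if (length(reads) == 0L || length(genome) == 0L) {
    cand <- data.frame(read_id = integer(0), ref_id = integer(0),
                       strand = character(0), pos = numeric(0),
                       score = numeric(0), cigar = character(0),
                       nm = integer(0), read_start = integer(0),
                       read_end = integer(0), kmer_score = numeric(0),
                       skeleton = numeric(0), stringsAsFactors = FALSE)
    res <- list(candidates = cand, unmappable = logical(length(reads)))
  } else {
    res <- pm_map_reads(unname(reads), unname(genome), pat$offsets, pat$span,
                        config$offset_gap, config$window_half_length,
                        config$kept_fraction, config$candidate_fraction,
                        config$kmer_params$m, config$kmer_params$g,
                        config$kmer_params$max_diagonal_drift,
                        config$bp_params$match, config$bp_params$mismatch,
                        config$bp_params$gap_open, config$bp_params$gap_extend,
                        config$band_pad, config$bisulfite,
                        config$expansion_cap)
  }
  cand <- res$candidates
  cand$read_name <- names(reads)[cand$read_id]
  cand$ref <- names(genome)[cand$ref_id]
  mappings <- select_best(cand, config$final_score_margin)
  if (nrow(mappings)) {
    full_cigar <- character(nrow(mappings))
    seq_out <- character(nrow(mappings))
    for (i in seq_len(nrow(mappings))) {
      rseq <- reads[[mappings$read_id[i]]]
      if (mappings$strand[i] == "-") rseq <- reverse_complement(rseq)
      seq_out[i] <- rseq
      n <- nchar(rseq)
      cg <- mappings$cigar[i]
      if (mappings$read_start[i] > 0)
        cg <- paste0(mappings$read_start[i], "S", cg)
      if (mappings$read_end[i] < n)
        cg <- paste0(cg, n - mappings$read_end[i], "S")
      full_cigar[i] <- cg
    }
    mappings$cigar <- full_cigar
    mappings$seq <- seq_out
  } else {
    mappings$seq <- character(0)
  }
  mapped_names <- unique(mappings$read_name)
  structure(list(mappings = mappings, candidates = cand,
                 unmapped = setdiff(names(reads), mapped_names),
                 reads = reads, genome = genome, config = config),
            class = "map_result")
}

#' Select final mappings per read
#'
#' Keeps, per read, the deduplicated candidates whose DP score is within
#' `final_score_margin` of that read's best; a read is flagged `unique`
#' when exactly one candidate survives.  Unique mappings get a MAPQ that
#' grows with the score gap to the runner-up (capped at 40, floor 1);
#' non-unique mappings get MAPQ 0.
#'
#' @param candidates Candidate data frame (from [map_reads()]'s buffer).
#' @param final_score_margin Non-negative score margin.
#' @return The filtered data frame with `unique` and `mapq` columns.
#' @export
select_best <- function(candidates, final_score_margin = 0) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    candidates$unique <- logical(0)
    candidates$mapq <- integer(0)
    return(candidates)
  }
  keep <- logical(nrow(candidates))
  mapq <- integer(nrow(candidates))
  uniq <- logical(nrow(candidates))
  for (rid in unique(candidates$read_id)) {
    sel <- which(candidates$read_id == rid)
    sc <- candidates$score[sel]
    best <- max(sc)
    kept <- sel[sc >= best - final_score_margin]
    keep[kept] <- TRUE
    is_unique <- length(kept) == 1L
    uniq[kept] <- is_unique
    if (is_unique) {
      runner <- if (length(sel) > 1L) max(sc[sc < best], -Inf) else -Inf
      gap <- if (is.finite(runner)) best - runner else best
      mapq[kept] <- as.integer(max(1, min(40, 1 + round(gap))))
    } else {
      mapq[kept] <- 0L
    }
  }
  out <- candidates[keep, , drop = FALSE]
  out$unique <- uniq[keep]
  out$mapq <- mapq[keep]
  rownames(out) <- NULL
  out
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf(
    "map_result: %d reads, %d final mappings (%d unique), %d unmapped\n",
    length(x$reads), nrow(x$mappings), sum(x$mappings$unique),
    length(x$unmapped)))
  invisible(x)
}
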