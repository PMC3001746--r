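#' Read a FASTA file
#'
#' Multi-line sequences are supported; lowercase is folded to uppercase;
#' the name is the header token before the first whitespace.
#'
#' @param path Path to a plain-text FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  is_header <- startsWith(lines, ">")
  if (length(lines)) {
    first_content <- which(keep)[1]
    if (!is.na(first_content) && !is_header[first_content])
      stop(sprintf("line %d: sequence data before any FASTA header",
                   first_content))
  }
  idx <- cumsum(is_header)
  headers <- sub("^>\\s*", "", lines[is_header])
  names_ <- sub("\\s.*$", "", headers)
  seqs <- vapply(seq_along(names_), function(i) {
    toupper(paste(lines[idx == i & !is_header & keep], collapse = ""))
  }, character(1))
  setNames(seqs, names_)
}

#' Read a FASTQ file
#'
#' Strict 4-line records.  Qualities are retained (as an attribute) but
#' unused by mapping.
#'
#' @param path Path to a plain-text FASTQ file.
#' @return Named character vector of uppercase sequences with attribute
#'   `qualities` (named character vector).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record: %d lines is not a multiple of 4",
                 length(lines)))
  n <- length(lines) %/% 4L
  nm <- character(n)
  sq <- character(n)
  ql <- character(n)
  for (i in seq_len(n)) {
    b <- (i - 1L) * 4L
    if (!startsWith(lines[b + 1L], "@"))
      stop(sprintf("line %d: expected '@' FASTQ header", b + 1L))
    if (!startsWith(lines[b + 3L], "+"))
      stop(sprintf("line %d: expected '+' separator", b + 3L))
    nm[i] <- sub("\\s.*$", "", sub("^@", "", lines[b + 1L]))
    sq[i] <- toupper(lines[b + 2L])
    ql[i] <- lines[b + 4L]
    if (nchar(sq[i]) != nchar(ql[i]))
      stop(sprintf("record '%s' (line %d): sequence and quality lengths differ (%d vs %d)",
                   nm[i], b + 2L, nchar(sq[i]), nchar(ql[i])))
  }
  out <- setNames(sq, nm)
  attr(out, "qualities") <- setNames(ql, nm)
  out
}

#' Read sequences from FASTA or FASTQ
#'
#' Dispatches on file extension (`.fq`/`.fastq` vs anything else).
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) read_fastq(path)
  else read_fasta(path)
}

#' Write a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, max(1L, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a FASTQ file with constant qualities
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param quality_char Constant per-base quality character.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep(quality_char, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Write mappings as SAM text
#'
#' Emits a @HD/@SQ/@PG header followed by one record per mapping (flags 0
#' or 16, 1-based POS, CIGAR with M/I/D/S, NM tag) and one flag-4 record
#' per unmapped read.  Internally all coordinates are 0-based half-open;
#' this is the single point of conversion to SAM's 1-based convention.
#'
#' @param x A `map_result` from [map_reads()], or a mappings data frame
#'   with columns `read_name`, `ref`, `pos` (0-based), `strand`, `mapq`,
#'   `cigar`, `seq`, `nm`.
#' @param path Output path (or `""` to return the lines invisibly only).
#' @param ref_lengths Named integer vector of reference lengths (taken
#'   from the `map_result` when `x` is one).
#' @param unmapped Named character vector of unmapped read sequences.
#' @return Invisibly, the SAM lines.
#' @export
write_sam <- function(x, path, ref_lengths = NULL, unmapped = NULL) {
  if (inherits(x, "map_result")) {
    ref_lengths <- setNames(nchar(x$genome), names(x$genome))
    unmapped <- x$reads[x$unmapped]
    x <- x$mappings
  }
  if (is.null(ref_lengths)) stop("ref_lengths required")
  bad <- setdiff(unique(x$ref), names(ref_lengths))
  if (length(bad))
    stop("mapping references unknown sequence: ", paste(bad, collapse = ", "))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)),
              "@PG\tID:poshmap\tPN:poshmap")
  rec <- character(0)
  if (!is.null(x) && nrow(x)) {
    flag <- ifelse(x$strand == "-", 16L, 0L)
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                   x$read_name, flag, x$ref, as.integer(x$pos) + 1L,
                   as.integer(x$mapq), x$cigar, x$seq, as.integer(x$nm))
  }
  urec <- character(0)
  if (length(unmapped)) {
    urec <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                    names(unmapped), unname(unmapped))
  }
  lines <- c(header, rec, urec)
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a BED file of regions
#'
#' Only the first three columns (chrom, 0-based start, end) plus an
#' optional name column are used.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `ref`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns")
  nm <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else rep(NA, nrow(tab))
  missing_nm <- is.na(nm) | !nzchar(nm)
  nm[missing_nm] <- paste0("region", which(missing_nm))
  data.frame(ref = tab[[1]], start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]), name = nm,
             stringsAsFactors = FALSE)
}

#' Write / read a simulator truth table
#'
#' Tab-separated, one row per read.
#'
#' @param truth Truth data frame (from a simulator).
#' @param path File path.
#' @name truth_io
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_io
#' @export
read_truth <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA, comment.char = "")
}

#' Parse mappings back out of a SAM file
#'
#' Minimal reader for the package's own SAM output (and any mapper's
#' single-end records): mandatory 11 columns plus an optional NM tag.
#'
#' @param path Path to a SAM text file.
#' @return Data frame with `read_name`, `flag`, `ref`, `pos` (0-based),
#'   `strand`, `mapq`, `cigar`, `seq`, `nm`, `unique` (MAPQ > 0).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_name = character(0), flag = integer(0),
                      ref = character(0), pos = numeric(0),
                      strand = character(0), mapq = integer(0),
                      cigar = character(0), seq = character(0),
                      nm = integer(0), unique = logical(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(f, function(x) {
    hit <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub("^NM:i:", "", hit[1])) else NA_integer_
  }, integer(1))
  flag <- as.integer(vapply(f, `[`, character(1), 2))
  data.frame(read_name = vapply(f, `[`, character(1), 1), flag = flag,
             ref = vapply(f, `[`, character(1), 3),
             pos = as.numeric(vapply(f, `[`, character(1), 4)) - 1,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapq = as.integer(vapply(f, `[`, character(1), 5)),
             cigar = vapply(f, `[`, character(1), 6),
             seq = vapply(f, `[`, character(1), 10), nm = nm,
             unique = as.integer(vapply(f, `[`, character(1), 5)) > 0L,
             stringsAsFactors = FALSE)
}
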