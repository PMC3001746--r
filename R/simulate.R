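ALT_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))

# replace each base by a uniformly chosen *different* base
other_base <- function(bases) {
  k <- sample.int(3L, length(bases), replace = TRUE)
  vapply(seq_along(bases), function(i) ALT_BASES[[bases[i]]][k[i]],
         character(1))
}

#' Generate a random genome sequence
#'
#' I.i.d. bases at the requested GC content; deterministic per seed.
#'
#' @param length Sequence length (bp).
#' @param gc_fraction Target GC fraction.
#' @param seed Optional RNG seed.
#' @param name Sequence name.
#' @return Named character vector of length 1 (empty string for length 0).
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                          name = "ref1") {
  if (!is.null(seed)) set.seed(seed)
  if (length == 0) return(setNames("", name))
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  setNames(paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                        prob = p), collapse = ""), name)
}

# i.i.d. substitutions at `rate`; every hit becomes a different base
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) chars[hit] <- other_base(chars[hit])
  paste(chars, collapse = "")
}

# Assemble a read from a template slice and an ordered list of events.
# Events: list(type = "S"/"I"/"D", t = 1-based template offset,
# base/seq/len).  Returns the emitted chars, template bases consumed and
# the edit tokens actually applied (0-based template offsets).
apply_events <- function(chars, events, read_length) {
  out <- character(0)
  edits <- character(0)
  t <- 1L
  L <- length(chars)
  for (ev in events) {
    if (ev$t < t) next  # swallowed by an earlier deletion
    need <- read_length - length(out)
    if (need <= 0L) break
    gapn <- ev$t - t
    take <- min(gapn, need)
    if (take > 0L) {
      out <- c(out, chars[t:(t + take - 1L)])
      t <- t + take
    }
    if (take < gapn) break  # read filled before reaching the event
    need <- read_length - length(out)
    if (need <= 0L) break
    if (ev$type == "S") {
      out <- c(out, ev$base)
      edits <- c(edits, sprintf("S%d:%s", t - 1L, ev$base))
      t <- t + 1L
    } else if (ev$type == "I") {
      ins <- ev$seq
      if (length(ins) > need) ins <- ins[seq_len(need)]
      out <- c(out, ins)
      edits <- c(edits, sprintf("I%d:%s", t - 1L, paste(ins, collapse = "")))
    } else {  # D
      edits <- c(edits, sprintf("D%d:%d", t - 1L, ev$len))
      t <- t + ev$len
    }
  }
  if (length(out) < read_length) {
    take <- min(read_length - length(out), L - t + 1L)
    if (take > 0L) {
      out <- c(out, chars[t:(t + take - 1L)])
      t <- t + take
    }
  }
  list(read = out, consumed = t - 1L, edits = edits)
}

#' Parse a truth-record edit string
#'
#' @param edits Semicolon-separated edit tokens (`S<t>:<base>`,
#'   `I<t>:<seq>`, `D<t>:<len>`, `B<t>:1`, `E<r>:<base>`); `""` for none.
#' @return Data frame with columns `type`, `t` (0-based offset) and
#'   `payload`.
#' @export
parse_edits <- function(edits) {
  if (is.na(edits) || !nzchar(edits))
    return(data.frame(type = character(0), t = integer(0),
                      payload = character(0), stringsAsFactors = FALSE))
  toks <- strsplit(edits, ";", fixed = TRUE)[[1]]
  data.frame(type = substr(toks, 1, 1),
             t = as.integer(sub("^[A-Z](\\d+):.*$", "\\1", toks)),
             payload = sub("^[A-Z]\\d+:", "", toks),
             stringsAsFactors = FALSE)
}

# pick, per read, a reference and a template-strand start position
pick_source <- function(genome, n, read_length, slack) {
  avail <- nchar(genome) - read_length - slack
  if (all(avail < 1))
    stop("genome sequences too short for read_length + slack")
  w <- pmax(avail, 0)
  ref_i <- if (length(genome) == 1L) rep(1L, n)
           else sample.int(length(genome), n, replace = TRUE, prob = w)
  start <- floor(runif(n) * avail[ref_i])  # 0-based on the template strand
  list(ref_i = ref_i, start = as.integer(start))
}

#' Simulate whole-genome shotgun reads
#'
#' Start positions are uniform and strands drawn uniformly.  Each template
#' basepair mutates with probability `mutation_rate`: a substitution with
#' probability `substitution_fraction`, otherwise an insertion or deletion
#' (equiprobable) of length uniform over `indel_range`.  Each emitted base
#' is then hit by a uniform sequencing error with probability `error_rate`
#' (substitution to a different base).  `fixed_indel_count` additionally
#' plants that many indels per read (length uniform over
#' `fixed_indel_range`), for variant-tolerance experiments.
#'
#' @param genome Named character vector of reference sequences.
#' @param n_reads Number of reads.
#' @param read_length Read length (bp).
#' @param mutation_rate Per-base mutation probability (default 0.001).
#' @param substitution_fraction Fraction of mutations that are
#'   substitutions (default 0.9); the rest are indels.
#' @param indel_range Integer range of mutation indel lengths (default 1:10).
#' @param error_rate Per-base sequencing error probability (default 0.02).
#' @param fixed_indel_count Planted indels per read (default 0).
#' @param fixed_indel_range Lengths for planted indels (default 1:5).
#' @param seed Optional RNG seed.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame: `read_id`, `name`, `ref`, `strand`, `start` — 0-based
#'   forward-strand leftmost coordinate of the template region —
#'   `consumed`, `edits`, `bisulfite = FALSE`).
#' @export
simulate_wgs_reads <- function(genome, n_reads, read_length,
                               mutation_rate = 0.001,
                               substitution_fraction = 0.9,
                               indel_range = 1:10, error_rate = 0.02,
                               fixed_indel_count = 0L,
                               fixed_indel_range = 1:5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- toupper(genome)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  slack <- 40L + 12L * fixed_indel_count
  src <- pick_source(genome, n_reads, read_length, slack)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- character(n_reads)
  truth <- vector("list", n_reads)
  rc_cache <- lapply(genome, reverse_complement)
  for (i in seq_len(n_reads)) {
    ref <- names(genome)[src$ref_i[i]]
    template <- if (strand[i] == "+") genome[[ref]] else rc_cache[[src$ref_i[i]]]
    len <- nchar(template)
    s0 <- src$start[i]
    chars <- strsplit(substr(template, s0 + 1L, s0 + read_length + slack),
                      "")[[1]]
    events <- list()
    if (mutation_rate > 0) {
      hits <- which(runif(length(chars)) < mutation_rate)
      for (h in hits) {
        if (runif(1) < substitution_fraction) {
          events[[length(events) + 1L]] <-
            list(type = "S", t = h, base = other_base(chars[h]))
        } else {
          ilen <- if (length(indel_range) == 1L) indel_range
                  else sample(indel_range, 1L)
          if (runif(1) < 0.5) {
            events[[length(events) + 1L]] <-
              list(type = "I", t = h,
                   seq = sample(c("A", "C", "G", "T"), ilen, replace = TRUE))
          } else {
            events[[length(events) + 1L]] <- list(type = "D", t = h, len = ilen)
          }
        }
      }
    }
    if (fixed_indel_count > 0L) {
      at <- sample.int(max(1L, read_length - 12L), fixed_indel_count)
      for (h in at) {
        ilen <- if (length(fixed_indel_range) == 1L) fixed_indel_range
                else sample(fixed_indel_range, 1L)
        if (runif(1) < 0.5) {
          events[[length(events) + 1L]] <-
            list(type = "I", t = h,
                 seq = sample(c("A", "C", "G", "T"), ilen, replace = TRUE))
        } else {
          events[[length(events) + 1L]] <- list(type = "D", t = h, len = ilen)
        }
      }
    }
    if (length(events) > 1L)
      events <- events[order(vapply(events, `[[`, numeric(1), "t"))]
    asm <- apply_events(chars, events, read_length)
    read_chars <- asm$read
    edits <- asm$edits
    if (error_rate > 0) {
      err <- which(runif(length(read_chars)) < error_rate)
      if (length(err)) {
        nb <- other_base(read_chars[err])
        read_chars[err] <- nb
        edits <- c(edits, sprintf("E%d:%s", err - 1L, nb))
      }
    }
    reads[i] <- paste(read_chars, collapse = "")
    fwd_start <- if (strand[i] == "+") s0 else len - (s0 + asm$consumed)
    truth[[i]] <- data.frame(
      read_id = i, name = paste0("read", i), ref = ref, strand = strand[i],
      start = fwd_start, consumed = asm$consumed,
      edits = paste(edits, collapse = ";"), bisulfite = FALSE,
      stringsAsFactors = FALSE)
  }
  names(reads) <- paste0("read", seq_len(n_reads))
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Simulate bisulfite-converted reads
#'
#' Reads are drawn uniformly from both strands.  Within each read, every
#' cytosine in CpG context is methylated with probability
#' `cpg_methylation_prob` (independently per read and site): methylated Cs
#' are preserved, unmethylated CpG Cs and all non-CpG Cs are converted to
#' T.  Optional uniform sequencing error follows.
#'
#' @inheritParams simulate_wgs_reads
#' @param cpg_methylation_prob Per-CpG per-read methylation probability.
#' @return List with `reads` and `truth`; truth carries `bisulfite = TRUE`
#'   and a `meth_states` column (`"<t>:<0|1>"` tokens for every CpG C in
#'   the template region, 0-based template-strand offsets).
#' @export
simulate_bisulfite_reads <- function(genome, n_reads, read_length,
                                     cpg_methylation_prob = 0.5,
                                     error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- toupper(genome)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  src <- pick_source(genome, n_reads, read_length, 1L)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- character(n_reads)
  truth <- vector("list", n_reads)
  rc_cache <- lapply(genome, reverse_complement)
  for (i in seq_len(n_reads)) {
    ref <- names(genome)[src$ref_i[i]]
    template <- if (strand[i] == "+") genome[[ref]] else rc_cache[[src$ref_i[i]]]
    len <- nchar(template)
    s0 <- src$start[i]
    chars <- strsplit(substr(template, s0 + 1L, s0 + read_length), "")[[1]]
    nxt <- if (s0 + read_length < len)
      substr(template, s0 + read_length + 1L, s0 + read_length + 1L) else ""
    cpos <- which(chars == "C")
    is_cpg <- vapply(cpos, function(p) {
      if (p < read_length) chars[p + 1L] == "G" else nxt == "G"
    }, logical(1))
    meth_at <- integer(0)
    states <- character(0)
    if (any(is_cpg)) {
      cg <- cpos[is_cpg]
      m <- rbinom(length(cg), 1L, cpg_methylation_prob)
      meth_at <- cg[m == 1L]
      states <- sprintf("%d:%d", cg - 1L, m)
    }
    read_chars <- chars
    conv <- setdiff(cpos, meth_at)
    read_chars[conv] <- "T"
    edits <- if (length(meth_at)) sprintf("B%d:1", sort(meth_at) - 1L)
             else character(0)
    if (error_rate > 0) {
      err <- which(runif(read_length) < error_rate)
      if (length(err)) {
        nb <- other_base(read_chars[err])
        read_chars[err] <- nb
        edits <- c(edits, sprintf("E%d:%s", err - 1L, nb))
      }
    }
    reads[i] <- paste(read_chars, collapse = "")
    fwd_start <- if (strand[i] == "+") s0 else len - (s0 + read_length)
    truth[[i]] <- data.frame(
      read_id = i, name = paste0("read", i), ref = ref, strand = strand[i],
      start = fwd_start, consumed = read_length,
      edits = paste(edits, collapse = ";"), bisulfite = TRUE,
      meth_states = paste(states, collapse = ";"), stringsAsFactors = FALSE)
  }
  names(reads) <- paste0("read", seq_len(n_reads))
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Simulate the unique/duplicated coevolution-speciation-divergence model
#'
#' A semi-repetitive benchmark: `n_unique` random ancestral tags plus one
#' ancestral tag copied `n_dup` times.  Each duplicated copy accumulates
#' independent substitutions at the coevolution rate `x` (gradually
#' acquiring uniqueness); the whole collection is then duplicated into two
#' species `r` and `s` (speciation), and every tag in both accumulates
#' independent substitutions at the divergence rate `y`.  Truth pairs
#' `r_i` with `s_i`.
#'
#' @param n_unique Number of unique ancestral tags.
#' @param n_dup Number of copies of the duplicated ancestral tag.
#' @param coevolution_rate Per-base substitution probability x.
#' @param divergence_rate Per-base substitution probability y.
#' @param read_length Tag length (bp).
#' @param gc_fraction GC content of the ancestral tags.
#' @param seed Optional RNG seed.
#' @return List with named character vectors `r` and `s` and a `truth`
#'   data frame pairing them (`name`, `ref`, `start = 0`, `strand = "+"`,
#'   `duplicated` flag).
#' @export
simulate_udcsd <- function(n_unique, n_dup, coevolution_rate,
                           divergence_rate, read_length = 200L,
                           gc_fraction = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coevolution_rate >= 0, coevolution_rate <= 1,
            divergence_rate >= 0, divergence_rate <= 1,
            n_unique >= 0, n_dup >= 0)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  rand_tag <- function() paste(sample(c("A", "C", "G", "T"), read_length,
                                      replace = TRUE, prob = p),
                               collapse = "")
  uniques <- vapply(seq_len(n_unique), function(i) rand_tag(), character(1))
  dup_anc <- if (n_dup > 0) rand_tag() else NULL
  dups <- vapply(seq_len(n_dup),
                 function(i) mutate_seq(dup_anc, coevolution_rate),
                 character(1))
  anc <- c(uniques, dups)
  n <- length(anc)
  r <- vapply(anc, mutate_seq, character(1), rate = divergence_rate,
              USE.NAMES = FALSE)
  s <- vapply(anc, mutate_seq, character(1), rate = divergence_rate,
              USE.NAMES = FALSE)
  names(r) <- paste0("r", seq_len(n))
  names(s) <- paste0("s", seq_len(n))
  truth <- data.frame(read_id = seq_len(n), name = names(r), ref = names(s),
                      strand = "+", start = 0L, consumed = read_length,
                      edits = "", bisulfite = FALSE,
                      duplicated = c(rep(FALSE, n_unique), rep(TRUE, n_dup)),
                      stringsAsFactors = FALSE)
  list(r = r, s = s, truth = truth)
}

#' Replay a truth record into its read
#'
#' Reconstructs a simulated read exactly from the genome and the recorded
#' edits, proving that the truth record is a faithful description.
#'
#' @param truth_row One row of a simulator truth data frame.
#' @param genome Named character vector of reference sequences.
#' @param detail Also return the template origin (0-based template-strand
#'   offset, NA for inserted bases) of every read base.
#' @param .template Precomputed template-strand sequence (internal cache
#'   hook for bulk replay).
#' @return The read string, or (with `detail = TRUE`) a list with `read`
#'   and `origin`.
#' @export
replay_read <- function(truth_row, genome, detail = FALSE, .template = NULL) {
  genome <- toupper(genome)
  ref <- genome[[truth_row$ref]]
  len <- nchar(ref)
  template <- if (!is.null(.template)) .template
              else if (truth_row$strand == "+") ref
              else reverse_complement(ref)
  s0 <- if (truth_row$strand == "+") truth_row$start
        else len - truth_row$start - truth_row$consumed
  chars <- strsplit(substr(template, s0 + 1L, s0 + truth_row$consumed),
                    "")[[1]]
  ed <- parse_edits(truth_row$edits)
  bis <- isTRUE(truth_row$bisulfite)
  meth_off <- ed$t[ed$type == "B"]  # 0-based template offsets of kept Cs
  ev <- ed[ed$type %in% c("S", "I", "D"), , drop = FALSE]
  ev <- ev[order(ev$t), , drop = FALSE]
  pieces <- list()
  origin <- list()
  copied <- list()
  t <- 1L
  push_copy <- function(upto) {  # copy template range [t, upto]
    if (upto >= t) {
      rng <- t:upto
      pieces[[length(pieces) + 1L]] <<- chars[rng]
      origin[[length(origin) + 1L]] <<- s0 + rng - 1L
      copied[[length(copied) + 1L]] <<- rep(TRUE, length(rng))
      t <<- upto + 1L
    }
  }
  for (ri in seq_len(nrow(ev))) {
    t0 <- ev$t[ri] + 1L
    push_copy(t0 - 1L)
    ty <- ev$type[ri]
    if (ty == "S") {
      pieces[[length(pieces) + 1L]] <- ev$payload[ri]
      origin[[length(origin) + 1L]] <- s0 + t0 - 1L
      copied[[length(copied) + 1L]] <- FALSE
      t <- t0 + 1L
    } else if (ty == "I") {
      ins <- strsplit(ev$payload[ri], "")[[1]]
      pieces[[length(pieces) + 1L]] <- ins
      origin[[length(origin) + 1L]] <- rep(NA_integer_, length(ins))
      copied[[length(copied) + 1L]] <- rep(FALSE, length(ins))
    } else {
      t <- t0 + as.integer(ev$payload[ri])
    }
  }
  push_copy(length(chars))
  out <- unlist(pieces, use.names = FALSE)
  origin <- unlist(origin, use.names = FALSE)
  copied <- unlist(copied, use.names = FALSE)
  if (bis) {
    conv <- copied & out == "C" & !((origin - s0) %in% meth_off)
    out[conv] <- "T"
  }
  err <- ed[ed$type == "E", , drop = FALSE]
  if (nrow(err)) out[err$t + 1L] <- err$payload
  if (detail) list(read = paste(out, collapse = ""), origin = origin)
  else paste(out, collapse = "")
}

#' Fraction of template-derived read bases that were changed
#'
#' Replays every truth record and reports the fraction of read bases with
#' a template origin (substitution sites, error sites and untouched copies
#' alike; inserted bases excluded) that differ from their template base.
#' For the default shotgun simulator rates this estimates
#' `error + mutation * substitution_fraction` up to second-order terms.
#'
#' @param truth Simulator truth data frame.
#' @param genome Named character vector of reference sequences.
#' @return List with `changed`, `total` and `fraction`.
#' @export
base_change_fraction <- function(truth, genome) {
  genome <- toupper(genome)
  tmpl_str <- new.env(parent = emptyenv())
  tmpl_chars <- new.env(parent = emptyenv())
  get_str <- function(ref, strand) {
    k <- paste0(strand, ref)
    v <- tmpl_str[[k]]
    if (is.null(v)) {
      v <- if (strand == "+") genome[[ref]] else reverse_complement(genome[[ref]])
      tmpl_str[[k]] <- v
    }
    v
  }
  get_chars <- function(ref, strand) {
    k <- paste0(strand, ref)
    v <- tmpl_chars[[k]]
    if (is.null(v)) {
      v <- strsplit(get_str(ref, strand), "")[[1]]
      tmpl_chars[[k]] <- v
    }
    v
  }
  changed <- 0L
  total <- 0L
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, , drop = FALSE]
    rp <- replay_read(row, genome, detail = TRUE,
                      .template = get_str(row$ref, row$strand))
    rd <- strsplit(rp$read, "")[[1]]
    keep <- !is.na(rp$origin)
    tb <- get_chars(row$ref, row$strand)[rp$origin[keep] + 1L]
    changed <- changed + sum(rd[keep] != tb)
    total <- total + sum(keep)
  }
  list(changed = changed, total = total, fraction = changed / total)
}

#' Evaluate mappings against simulator truth
#'
#' A uniquely mapped read is a true positive when its reference and strand
#' match the truth and its leftmost position is within
#' `position_tolerance` of the true start.  TPR divides true positives by
#' all simulated reads; PPV divides them by the number of reported unique
#' mappings.
#'
#' @param mappings A `map_result` or a mappings data frame with columns
#'   `read_name`, `ref`, `pos` (0-based), `strand`, `unique`.
#' @param truth Simulator truth data frame.
#' @param position_tolerance Allowed |mapped - true| start distance (bp);
#'   `Inf` disables the positional check (reference/strand only).
#' @return A list of class `eval_result`: `tpr`, `ppv`, `tp`, `n_reads`,
#'   `n_unique`.
#' @export
evaluate_mappings <- function(mappings, truth, position_tolerance = 5) {
  if (inherits(mappings, "map_result")) mappings <- mappings$mappings
  unknown <- setdiff(mappings$read_name, truth$name)
  if (length(unknown))
    stop("mappings reference read ids absent from truth: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  um <- mappings[mappings$unique, , drop = FALSE]
  ti <- match(um$read_name, truth$name)
  tp <- sum(um$ref == truth$ref[ti] & um$strand == truth$strand[ti] &
              abs(um$pos - truth$start[ti]) <= position_tolerance)
  structure(list(tpr = tp / nrow(truth), ppv = if (nrow(um)) tp / nrow(um)
                 else NA_real_, tp = tp, n_reads = nrow(truth),
                 n_unique = nrow(um)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TPR %.4f (%d/%d)  PPV %s (%d unique mappings)\n", x$tpr,
              x$tp, x$n_reads,
              if (is.na(x$ppv)) "NA" else sprintf("%.4f", x$ppv),
              x$n_unique))
  invisible(x)
}
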