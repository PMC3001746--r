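# Independent oracles used across the suite.  These deliberately share no
# code with the package internals they check.

# ovl(d) by explicit shifted-set intersection
ovl_bruteforce <- function(offsets, span) {
  vapply(0:span, function(d) {
    s <- span - d
    length(intersect(offsets, offsets + s))
  }, integer(1))
}

# draw a random valid 0/1 pattern of span <= max_span
random_pattern <- function(max_span = 32L) {
  span <- sample(2:max_span, 1L)
  bits <- sample(c("0", "1"), span, replace = TRUE)
  bits[1] <- "1"
  bits[span] <- "1"
  paste(bits, collapse = "")
}

# Full-matrix affine-gap local DP with the same scoring and tie-breaking
# conventions as the package (source preference M > D > I > start; gap
# states prefer opening on ties; best cell = first maximal M cell in
# (i, j) scan order), written directly from the recurrences with plain R
# matrices.  Returns score, cigar (with soft clips) and intervals.
full_dp_oracle <- function(read, ref, match = 1, mismatch = 2, gap_open = 2,
                           gap_extend = 1, bisulfite = FALSE) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  n <- length(rd)
  m <- length(rf)
  M <- matrix(-Inf, n + 1, m + 1)
  D <- matrix(-Inf, n + 1, m + 1)
  I <- matrix(-Inf, n + 1, m + 1)
  tM <- matrix(0L, n + 1, m + 1)
  tD <- matrix(0L, n + 1, m + 1)
  tI <- matrix(0L, n + 1, m + 1)
  best <- 0
  bi <- -1L
  bj <- -1L
  for (i in 1:n) {
    for (j in 1:m) {
      is_match <- rd[i] == rf[j] || (bisulfite && rd[i] == "T" && rf[j] == "C")
      s <- if (is_match) match else -mismatch
      bprev <- 0
      src <- 0L
      if (M[i, j] >= bprev) { bprev <- M[i, j]; src <- 1L }
      if (D[i, j] > bprev) { bprev <- D[i, j]; src <- 2L }
      if (I[i, j] > bprev) { bprev <- I[i, j]; src <- 3L }
      M[i + 1, j + 1] <- s + bprev
      tM[i + 1, j + 1] <- src
      open_d <- M[i + 1, j] - gap_open - gap_extend
      ext_d <- D[i + 1, j] - gap_extend
      if (open_d >= ext_d) { D[i + 1, j + 1] <- open_d; tD[i + 1, j + 1] <- 1L }
      else { D[i + 1, j + 1] <- ext_d; tD[i + 1, j + 1] <- 2L }
      open_i <- M[i, j + 1] - gap_open - gap_extend
      ext_i <- I[i, j + 1] - gap_extend
      if (open_i >= ext_i) { I[i + 1, j + 1] <- open_i; tI[i + 1, j + 1] <- 1L }
      else { I[i + 1, j + 1] <- ext_i; tI[i + 1, j + 1] <- 2L }
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]
        bi <- i
        bj <- j
      }
    }
  }
  if (bi < 0) return(list(score = 0, cigar = "", read_start = 0L,
                          read_end = 0L, ref_start = 0L, ref_end = 0L))
  ops <- character(0)
  i <- bi
  j <- bj
  state <- 1L
  repeat {
    if (state == 1L) {
      ops <- c("M", ops)
      src <- tM[i + 1, j + 1]
      i <- i - 1L
      j <- j - 1L
      if (src == 0L) break
      state <- src
    } else if (state == 2L) {
      ops <- c("D", ops)
      src <- tD[i + 1, j + 1]
      j <- j - 1L
      state <- if (src == 1L) 1L else 2L
    } else {
      ops <- c("I", ops)
      src <- tI[i + 1, j + 1]
      i <- i - 1L
      state <- if (src == 1L) 1L else 3L
    }
  }
  r <- rle(ops)
  cig <- paste0(r$lengths, r$values, collapse = "")
  if (i > 0) cig <- paste0(i, "S", cig)
  if (bi < n) cig <- paste0(cig, n - bi, "S")
  list(score = best, cigar = cig, read_start = i, read_end = bi,
       ref_start = j, ref_end = bj)
}

# mutate a sequence at fixed positions (1-based) to the next base in ACGT
force_mismatches <- function(seq, at) {
  chars <- strsplit(seq, "")[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  chars[at] <- nxt[chars[at]]
  paste(chars, collapse = "")
}

# random sequence pair at a given divergence, for DP oracle comparisons
random_diverged_pair <- function(len, divergence) {
  a <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  chars <- strsplit(a, "")[[1]]
  hit <- which(runif(len) < divergence)
  for (h in hit) chars[h] <- sample(setdiff(c("A", "C", "G", "T"), chars[h]), 1)
  list(read = a, ref = paste(chars, collapse = ""))
}
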