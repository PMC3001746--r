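small_cfg <- function(...) {
  mapper_config(read_length = 60L, window_half_length = 500L,
                preset = "high", ...)
}

test_that("stream_windows tiles with stride W and 50% overlap", {
  g <- c(chrA = strrep("A", 100))
  w <- stream_windows(g, 30)
  expect_equal(w$start, c(0L, 30L, 60L, 90L))
  expect_equal(nchar(w$seq), c(60L, 60L, 40L, 10L))
  # short sequence: a single window
  w2 <- stream_windows(c(s = strrep("C", 50)), 30)
  expect_equal(nrow(w2), 1L)
  # windows never span sequence boundaries
  w3 <- stream_windows(c(a = strrep("A", 70), b = strrep("C", 40)), 30)
  lens <- c(a = 70L, b = 40L)
  expect_true(all(w3$start + nchar(w3$seq) <= lens[w3$ref]))
  expect_false(any(grepl("C", w3$seq[w3$ref == "a"])))
})

test_that("presets set kept_fraction and scale G with read length", {
  expect_equal(preset_params("fast", 100L)$kept_fraction, 0.93)
  for (p in c("high", "medium", "low"))
    expect_equal(preset_params(p, 100L)$kept_fraction, 0.99)
  g_low <- preset_params("low", 200L)$offset_gap
  expect_gte(g_low, 8L)
  expect_lte(g_low, 25L)
  expect_equal(preset_params("high", 100L)$offset_gap, 7L)
  expect_error(preset_params("turbo"), "arg")
})

test_that("a planted read maps uniquely to its position on either strand", {
  g <- random_genome(50000, seed = 11, name = "chr1")
  read <- unname(substr(g, 1001, 1060))
  res <- map_reads(c(r1 = read, r2 = reverse_complement(read)), g,
                   small_cfg())
  m <- res$mappings
  expect_equal(nrow(m), 2L)
  expect_equal(m$pos, c(1000, 1000))
  expect_equal(m$strand, c("+", "-"))
  expect_equal(m$cigar, c("60M", "60M"))
  expect_true(all(m$unique))
  expect_true(all(m$mapq > 0))
  sam <- write_sam(res, "")
  rec <- strsplit(grep("^[^@]", sam, value = TRUE), "\t")
  expect_equal(vapply(rec, `[`, character(1), 2), c("0", "16"))
  expect_equal(vapply(rec, `[`, character(1), 4), c("1001", "1001"))
})

test_that("a deletion in the read yields a D op at the right place", {
  g <- random_genome(30000, seed = 13, name = "chr1")
  read <- paste0(substr(g, 5001, 5030), substr(g, 5034, 5063))
  res <- map_reads(c(d = read), g, small_cfg())
  expect_equal(nrow(res$mappings), 1L)
  expect_match(res$mappings$cigar, "3D")
  expect_equal(res$mappings$pos, 5000)
  ins_read <- paste0(substr(g, 8001, 8030), "ACGT", substr(g, 8031, 8056))
  res2 <- map_reads(c(i = ins_read), g, small_cfg())
  expect_match(res2$mappings$cigar, "4I")
})

test_that("a read present at two loci is reported non-unique", {
  core <- random_genome(2000, seed = 17)
  g <- c(chr1 = paste0(unname(core),
                       unname(random_genome(1000, seed = 18)),
                       unname(core)))
  read <- substr(core, 501, 560)
  res <- map_reads(c(r = unname(read)), g, small_cfg())
  expect_equal(nrow(res$mappings), 2L)
  expect_false(any(res$mappings$unique))
  expect_true(all(res$mappings$mapq == 0L))
})

test_that("select_best applies the score margin and unique flag", {
  cand <- data.frame(read_id = 1L, ref_id = 1L, strand = "+",
                     pos = c(10, 50, 90), score = c(100, 98, 90),
                     cigar = "10M", nm = 0L, read_start = 0L,
                     read_end = 10L, kmer_score = 0, skeleton = 0,
                     read_name = "r", ref = "c", stringsAsFactors = FALSE)
  kept <- select_best(cand, 5)
  expect_equal(nrow(kept), 2L)
  expect_false(any(kept$unique))
  kept0 <- select_best(cand, 0)
  expect_equal(nrow(kept0), 1L)
  expect_true(kept0$unique)
  expect_gt(kept0$mapq, 0L)
})

test_that("empty inputs produce an empty result with a valid SAM header", {
  g <- c(chr1 = "ACGTACGTACGTACGTACGTACGT")
  res <- map_reads(character(0), g,
                   mapper_config(read_length = 10L, pattern = "111"))
  expect_equal(nrow(res$mappings), 0L)
  sam <- write_sam(res, "")
  expect_match(sam[1], "^@HD")
  expect_match(sam[2], "^@SQ\tSN:chr1\tLN:24$")
})

test_that("unmapped reads are emitted with flag 4", {
  g <- random_genome(5000, seed = 19, name = "chr1")
  res <- map_reads(c(x = strrep("ACGT", 15)), g, small_cfg())
  sam <- write_sam(res, "")
  rec <- grep("^x\t", sam, value = TRUE)
  expect_length(rec, 1L)
  expect_equal(strsplit(rec, "\t")[[1]][2], "4")
})

test_that("strand symmetry: reverse-complemented reads mirror exactly", {
  g <- random_genome(40000, seed = 23, name = "chr1")
  sim <- simulate_wgs_reads(g, 40, 60, mutation_rate = 0.005,
                            error_rate = 0.01, seed = 29)
  cfg <- small_cfg()
  fwd <- map_reads(sim$reads, g, cfg)$mappings
  rcv <- map_reads(setNames(reverse_complement(sim$reads),
                            names(sim$reads)), g, cfg)$mappings
  norm <- function(m) m[order(m$read_name, m$pos),
                        c("read_name", "ref", "pos", "score", "cigar", "nm",
                          "seq")]
  a <- norm(fwd)
  b <- norm(rcv)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  flipped <- ifelse(fwd$strand == "+", "-", "+")
  expect_identical(rcv[order(rcv$read_name, rcv$pos), "strand"],
                   flipped[order(fwd$read_name, fwd$pos)])
})

test_that("window-overlap dedup leaves one candidate per locus", {
  g <- random_genome(3000, seed = 31, name = "chr1")
  # plant a read across the boundary region shared by two windows
  read <- unname(substr(g, 481, 540))
  res <- map_reads(c(r = read), g, small_cfg())
  expect_equal(nrow(res$candidates[res$candidates$score ==
                                     max(res$candidates$score), ]), 1L)
  expect_equal(res$mappings$pos, 480)
})

test_that("lowering candidate_fraction never removes final mappings", {
  g <- random_genome(20000, seed = 37, name = "chr1")
  sim <- simulate_wgs_reads(g, 60, 60, mutation_rate = 0.01, seed = 41)
  key <- function(cfrac) {
    res <- map_reads(sim$reads, g, small_cfg(candidate_fraction = cfrac))
    with(res$mappings, paste(read_name, ref, pos, strand))
  }
  strict <- key(0.75)
  loose <- key(0.4)
  expect_true(all(strict %in% loose))
})

test_that("bisulfite mapping recovers fully converted reads on both strands", {
  g <- random_genome(20000, seed = 43, name = "chr1")
  sim <- simulate_bisulfite_reads(g, 40, 60, cpg_methylation_prob = 0,
                                  seed = 47)
  cfg <- mapper_config(bisulfite = TRUE, preset = "high", read_length = 60L)
  res <- map_reads(sim$reads, g, cfg)
  ev <- evaluate_mappings(res, sim$truth, 5)
  expect_equal(ev$tpr, 1.0)
  expect_equal(ev$ppv, 1.0)
  expect_true(all(res$mappings$nm == 0))  # conversions are not edits
})

test_that("mapping runs are deterministic", {
  g <- random_genome(15000, seed = 53, name = "chr1")
  sim <- simulate_wgs_reads(g, 30, 60, seed = 59)
  a <- map_reads(sim$reads, g, small_cfg())$mappings
  b <- map_reads(sim$reads, g, small_cfg())$mappings
  expect_identical(a, b)
})
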