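test_that("random_genome hits the requested length and GC", {
  expect_equal(unname(random_genome(0, seed = 1)), "")
  at_only <- random_genome(500, gc_fraction = 0, seed = 2)
  expect_false(grepl("[GC]", at_only))
  g <- random_genome(100000, gc_fraction = 0.4, seed = 3)
  gc <- sum(strsplit(unname(g), "")[[1]] %in% c("G", "C"))
  sigma <- sqrt(100000 * 0.4 * 0.6)
  expect_lt(abs(gc - 40000), 3 * sigma)
})

test_that("generators are bit-reproducible per seed", {
  g <- random_genome(5000, seed = 5)
  a <- simulate_wgs_reads(g, 50, 80, seed = 7)
  b <- simulate_wgs_reads(g, 50, 80, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_wgs_reads(g, 50, 80, seed = 8)))
  u1 <- simulate_udcsd(20, 5, 0.2, 0.02, 100, seed = 9)
  u2 <- simulate_udcsd(20, 5, 0.2, 0.02, 100, seed = 9)
  expect_identical(u1, u2)
  s1 <- simulate_bisulfite_reads(g, 30, 60, seed = 11)
  s2 <- simulate_bisulfite_reads(g, 30, 60, seed = 11)
  expect_identical(s1, s2)
})

test_that("error-free shotgun reads are exact genome substrings", {
  g <- random_genome(20000, seed = 13, name = "chrZ")
  sim <- simulate_wgs_reads(g, 100, 70, mutation_rate = 0, error_rate = 0,
                            seed = 17)
  for (i in sample(100, 20)) {
    row <- sim$truth[i, ]
    slice <- substr(g[[row$ref]], row$start + 1, row$start + 70)
    if (row$strand == "-") slice <- reverse_complement(slice)
    expect_identical(unname(sim$reads[[i]]), slice)
  }
  expect_true(all(sim$truth$edits == ""))
})

test_that("truth edits replay every read exactly", {
  g <- random_genome(30000, seed = 19)
  sim <- simulate_wgs_reads(g, 1000, 80, mutation_rate = 0.01,
                            error_rate = 0.02, seed = 23)
  ok <- vapply(seq_len(1000), function(i)
    replay_read(sim$truth[i, ], g) == sim$reads[[i]], logical(1))
  expect_true(all(ok))
  simb <- simulate_bisulfite_reads(g, 300, 60, cpg_methylation_prob = 0.5,
                                   error_rate = 0.01, seed = 29)
  okb <- vapply(seq_len(300), function(i)
    replay_read(simb$truth[i, ], g) == simb$reads[[i]], logical(1))
  expect_true(all(okb))
})

test_that("base-change fraction matches error + substitution rates", {
  g <- random_genome(30000, seed = 31)
  sim <- simulate_wgs_reads(g, 2500, 100, seed = 37)  # 2.5e5 bases
  st <- base_change_fraction(sim$truth, g)
  p <- 0.02 + 0.001 * 0.9
  expect_lt(abs(st$fraction - p), 3 * sqrt(p * (1 - p) / st$total))
})

test_that("mutation indel lengths are uniform on the stated range", {
  g <- random_genome(60000, seed = 41)
  # push the mutation rate up and make every mutation an indel
  sim <- simulate_wgs_reads(g, 300, 100, mutation_rate = 0.05,
                            substitution_fraction = 0, error_rate = 0,
                            seed = 43)
  ed <- do.call(rbind, lapply(sim$truth$edits, parse_edits))
  lens <- c(nchar(ed$payload[ed$type == "I"]),
            as.integer(ed$payload[ed$type == "D"]))
  expect_gt(length(lens), 1000L)
  tab <- tabulate(lens, nbins = 10)
  p <- suppressWarnings(stats::chisq.test(tab, p = rep(0.1, 10))$p.value)
  expect_gt(p, 0.01)
})

test_that("UD-CSD honours its degenerate and statistical contracts", {
  # x = y = 0: species copies are identical
  sim0 <- simulate_udcsd(30, 10, 0, 0, 100, seed = 47)
  expect_identical(unname(sim0$r), unname(sim0$s))
  expect_equal(sum(sim0$truth$duplicated), 10L)
  # pairwise divergence matches the i.i.d. substitution expectation
  y <- 0.05
  sim <- simulate_udcsd(1000, 0, 0.25, y, 200, seed = 53)
  hd <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), sim$r, sim$s)
  q <- 2 * y * (1 - y) + (2 / 3) * y^2
  expect_lt(abs(mean(hd) / 200 - q), 3 * sqrt(q * (1 - q) / (1000 * 200)))
})

test_that("bisulfite conversion follows the methylation states", {
  g <- random_genome(20000, seed = 59)
  full <- simulate_bisulfite_reads(g, 50, 60, cpg_methylation_prob = 1,
                                   seed = 61)
  for (i in 1:50) {  # methylated CpG Cs retained; all other Cs converted
    row <- full$truth[i, ]
    tmpl <- if (row$strand == "+") g[[row$ref]]
            else reverse_complement(g[[row$ref]])
    s0 <- if (row$strand == "+") row$start
          else nchar(tmpl) - row$start - 60
    slice_plus <- substr(tmpl, s0 + 1, s0 + 61)  # one base of context
    cpg_c <- as.integer(gregexpr("CG", slice_plus)[[1]])
    cpg_c <- cpg_c[cpg_c >= 1 & cpg_c <= 60]
    read_c <- as.integer(gregexpr("C", full$reads[[i]])[[1]])
    read_c <- read_c[read_c >= 1]
    expect_identical(read_c, cpg_c, info = i)
  }
  none <- simulate_bisulfite_reads(g, 50, 60, cpg_methylation_prob = 0,
                                   seed = 67)
  expect_false(any(grepl("C", none$reads)))
  # methylation frequency approaches the Bernoulli parameter
  half <- simulate_bisulfite_reads(g, 2700, 60, cpg_methylation_prob = 0.5,
                                   seed = 71)
  states <- unlist(lapply(half$truth$meth_states, function(s) {
    if (!nzchar(s)) return(integer(0))
    as.integer(sub(".*:", "", strsplit(s, ";")[[1]]))
  }))
  expect_gt(length(states), 5000L)
  expect_lt(abs(mean(states) - 0.5), 3 * sqrt(0.25 / length(states)))
})

test_that("evaluate counts true positives by locus, strand and tolerance", {
  truth <- data.frame(read_id = 1:10, name = paste0("read", 1:10),
                      ref = "chr1", strand = "+", start = (1:10) * 100,
                      stringsAsFactors = FALSE)
  m <- data.frame(read_name = paste0("read", 1:8), ref = "chr1",
                  pos = c((1:6) * 100 + 3, 9999, 9999), strand = "+",
                  unique = TRUE, stringsAsFactors = FALSE)
  ev <- evaluate_mappings(m, truth, 5)
  expect_equal(ev$tpr, 0.6)
  expect_equal(ev$ppv, 0.75)
  # 5 unique-correct, 5 unmapped
  ev2 <- evaluate_mappings(m[1:5, ], truth, 5)
  expect_equal(ev2$tpr, 0.5)
  expect_equal(ev2$ppv, 1.0)
  # unknown read id is an integrity error
  bad <- m
  bad$read_name[1] <- "ghost"
  expect_error(evaluate_mappings(bad, truth, 5), "ghost")
})

test_that("mapper TPR is anti-monotone in simulated error rate", {
  g <- random_genome(30000, seed = 73, name = "chr1")
  cfg <- mapper_config(preset = "medium", read_length = 80L)
  tprs <- vapply(c(0.01, 0.06, 0.15), function(e) {
    sim <- simulate_wgs_reads(g, 150, 80, mutation_rate = 0, error_rate = e,
                              seed = 79)
    evaluate_mappings(map_reads(sim$reads, g, cfg), sim$truth, 5)$tpr
  }, numeric(1))
  expect_true(all(diff(tprs) <= 0))
  expect_gt(tprs[1], 0.9)
})
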