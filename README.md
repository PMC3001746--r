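# poshmap

A read mapper built on **positional hashing of gapped k-mer patterns**, for
single-end genomic and bisulfite sequencing reads, together with the read
simulators and TPR/PPV evaluation needed to benchmark every stage of the
pipeline on synthetic data.

## Who this is for

Researchers and tool builders who need a transparent, fully inspectable
mapping pipeline: every stage — gapped-pattern sampling, the
multi-positional hash index, k-mer-level chaining, skeleton filtering,
banded dynamic programming, SAM output, bisulfite handling, methylation
calling — is an exported, separately testable R function, with the hot
loops in C++ (Rcpp).

## The method

A *gapped pattern* (spaced seed) `P` is a 0/1 mask of span `s` and weight
`t`; a k-mer match between sequences `S` and `T` at positions `i`, `j`
requires `S[i + x] = T[j + x]` only at the sampled offsets `x` of `P`.
Reads are indexed once in a single **multi-positional hash table**: each
key maps to entries `(read, offset)` for offsets `0, G, 2G, …` plus the
terminal offset, so one table serves every sampling position.  The genome
is never indexed — it is streamed in windows of length `2W` (stride `W`,
50% overlap) against the read index.

Matching k-mers for a read × window pair are chained by a greedy
**k-mer-level alignment**: a match extends the best-scoring collinear run,
adding

```
(t − ovl(d))·m − g·gap
```

where `ovl(d)` is the number of sampled positions two placements of `P`
share when they overlap by `d` bp (so no sampled base is rewarded twice),
`m` is the per-base match reward, and `gap` the diagonal change.  Runs
passing a running-best fraction filter (default 3/4) are scored by an
affine **skeleton bound**; survivors of a second 3/4 filter get a banded
affine-gap Smith-Waterman restricted to the run's diagonals, and the best
candidates per read are reported as SAM text with `NM` tags, uniqueness
and MAPQ.

For **bisulfite-treated reads** (unmethylated C read as T), every sampled
read k-mer is expanded by converting each T to either C or T before
hashing, both strands of the reference are streamed, and read-T/ref-C is
scored as a match.  Downstream utilities remove monoclonal (duplicate)
reads, call per-cytosine methylation at ≥ 5× informative coverage with
CpG/CHG/CHH context, and compute the agreement-ratio contingency analysis
for imprinting-style comparisons.

Three simulators close the loop: uniform whole-genome shotgun reads with
0.1% mutation (90% substitutions, 10% indels of 1–10 bp) and 2% uniform
sequencing error; a unique/duplicated–coevolution/speciation/divergence
(UD-CSD) benchmark for semi-repetitive genomes; and bisulfite conversion
with per-CpG methylation probability.  Each simulator emits a truth table
whose edits replay into the exact read, and `evaluate_mappings()` computes
TPR (true positives / all reads) and PPV (true positives / unique
mappings).

## Worked example

```r
library(poshmap)
genome <- random_genome(50000, gc_fraction = 0.45, seed = 101, name = "chr1")
sim    <- simulate_wgs_reads(genome, n_reads = 200, read_length = 100, seed = 102)
cfg    <- mapper_config(preset = "high", read_length = 100)
res    <- map_reads(sim$reads, genome, cfg)
res
#> map_result: 200 reads, 200 final mappings (200 unique), 0 unmapped
head(res$mappings[, c("read_name","ref","pos","strand","score","cigar","nm","mapq")], 3)
#>   read_name  ref   pos strand score cigar nm mapq
#> 1     read1 chr1 21399      -    97  100M  1   40
#> 2     read2 chr1 25325      -    97  100M  1   40
#> 3     read3 chr1 10825      -    91  100M  3   40
evaluate_mappings(res, sim$truth, position_tolerance = 5)
#> TPR 1.0000 (200/200)  PPV 1.0000 (200 unique mappings)
write_sam(res, "out.sam")
```

`pos` is 0-based internally; the SAM writer performs the single conversion
to 1-based `POS`.  `score` is the banded-DP alignment score (+1 match, −2
mismatch, gap `−2 − 1·len` by default), `nm` the edit distance: read1
carries one simulated mutation/error, hence score 97 = 99·(+1) − 2.

A command-line interface wrapping the same functions ships in
`inst/cli/poshmap`:

```sh
poshmap simulate wgs --ref ref.fa --n-reads 1000 --reads-out reads.fq --truth-out truth.tsv
poshmap map --reads reads.fq --ref ref.fa --preset high --out out.sam
poshmap evaluate --sam out.sam --truth truth.tsv --tolerance 5
```

## Layout

| Where | What |
|---|---|
| `R/patterns.R` | gapped patterns, `sample_kmer()`, `overlap_table()` |
| `R/index.R` | multi-positional hash index, bisulfite k-mer expansion |
| `R/kmer_align.R` | greedy run extension (`kmer_align()`) |
| `R/bp_align.R` | skeleton bound, banded DP, CIGAR utilities |
| `R/mapper.R` | window streaming, filters, `map_reads()`, `select_best()` |
| `R/methylome.R` | monoclonal removal, methylation calls, agreement ratio |
| `R/simulate.R` | WGS / UD-CSD / bisulfite simulators, truth replay, TPR/PPV |
| `R/io.R` | FASTA/FASTQ/SAM/BED/truth readers and writers |
| `R/cli.R`, `inst/cli/poshmap` | command-line interface |
| `src/` | C++ kernels (index, chaining, banded DP, pipeline) |
| `vignettes/positional-hashing.Rmd` | methods notes: model, parameters, limits |
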