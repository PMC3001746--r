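---
title: "Positional hashing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional hashing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements:
what the model is, what each tunable means, what the synthetic-data
generators do and do not emulate, and where the design was genuinely open
and a choice had to be committed.  No empirical number is stated here that
the test suite does not itself compute.

## The model

### Gapped k-mer matches

A gapped pattern (spaced seed) is a 0/1 mask; its *span* is the mask
length, its *weight* `t` the number of sampled positions.  Two sequences
match at a position pair when they agree at every sampled offset.
Compared with contiguous k-mers of the same weight, gapped patterns
decorrelate neighbouring match tests and tolerate substitutions falling
on unsampled positions.  Any position holding a non-ACGT code at a
*sampled* offset voids that k-mer; unsampled positions are ignored, since
they never participate in the match definition.

The package ships two defaults: `111011011000110101` (span 18, weight 11)
for ordinary mapping and `111010110100110111` (span 18, weight 12) for
bisulfite mapping, both user-overridable via `--pattern` or
`mapper_config(pattern=)`.  The ordinary-mapping default derives from a
published pattern whose printed form carries a trailing `0`; because a
trailing unsampled position can never participate in a match and the
parser (by contract) rejects leading/trailing zeros, the default trims it.

### The multi-positional hash index

Reads — never the genome — are indexed.  Each read is sampled at offsets
`0, G, 2G, …` plus the terminal offset `length − span`, so both read ends
are always covered regardless of divisibility (the terminal-offset rule is
this package's choice; the method description leaves sampling positions
open).  Entries are `(read, offset, orientation)` under the packed k-mer
key; a single table holds all offsets, which is what distinguishes
multi-positional hashing from one-table-per-offset schemes and avoids any
disk-based inversion step.

High-frequency k-mers may be discarded for speed (`kept_fraction`,
default 0.99; the `fast` preset uses 0.93).  Two safeguards keep this a
pure speed knob:

* a frequency class is never split — keys tied with the boundary
  frequency all survive, so equally common k-mers share one fate and no
  arbitrary tie order is needed;
* a key is only discardable when genuinely overrepresented: its entry
  count must exceed both twice the mean entries-per-key and an absolute
  floor of 10.

The second rule matters at small scale.  In a batch of a few thousand
lightly overlapping reads the frequency distribution is near-uniform
(counts 1–3 arise from coverage coincidence, e.g. a read and the exact
reverse complement of another read drawn at the same locus); a pure
rank-based top-1% cut would delete precisely those keys and silently make
the affected reads unmappable, while removing nothing repetitive.  On
repeat-rich data at scale, overrepresented keys have counts orders of
magnitude above the mean and the filter behaves as the rank rule
describes.  The k-mer-space cap in bisulfite mode (below) is the same
kind of guard.

### K-mer-level alignment

Matches between one read and one genomic window, sorted by
`(read_offset, window_offset)`, are chained greedily.  A match *extends* a
run when it is strictly collinear in both coordinates and its diagonal
drifts by at most `max_diagonal_drift` (default 10 bp) from the run's last
k-mer.  The extension reward is `(t − ovl(d))·m − g·gap`, where
`d = max(0, span − Δread)` is the basepair overlap of the two pattern
placements, `ovl(d)` the number of sampled positions those placements
share, and `gap = |Δdiagonal|` the net indel bases implied.  `ovl`
prevents double-paying for sampled bases covered by both k-mers: for a
contiguous pattern the best gap-free chain score equals exactly the number
of distinct matched positions, a property the tests exploit as an oracle.

Two aspects of the published pseudocode are contradictory or undefined,
and this package commits to:

* **all live runs are evaluated** and the best-scoring extension taken
  (the pseudocode also contains a first-hit `break`; the best-extension
  semantics dominates it in accuracy and matches the intent of tracking a
  best extension score across runs);
* **"extends" means** strict collinearity plus the bounded diagonal
  drift above, echoing chaining across a small number of neighbouring
  diagonals; runs are linear chains — once extended, a run's previous
  endpoint is not available for branching.

A non-extending match starts a new run scored `t·m`.  Ties between
equally scoring runs go to the smallest window offset, for determinism.
Defaults `m = 1`, `g = 2` are this package's choice (the method fixes no
numbers) and are exposed in `kmer_scoring_params()`.

### Skeleton filter and banded DP

Candidate runs pass two running-best filters (both default 3/4, the
`candidate_fraction`): first on the k-mer chain score, then on a
*skeleton* score — an affine estimate of the basepair score computed in
k-mer space:

```
match_reward · (read positions covered by the union of k-mer spans)
  − gap_open · (number of diagonal shifts)
  − gap_extend · (total |Δdiagonal|)
```

The published description says only that bounds on an approximate
alignment score are evaluated with an affine function; the formula above
is this package's committed interpretation, isolated behind
`skeleton_score()` so it can be swapped.  It is *not* asserted to bound
the DP score; the tests assert instead that it is monotone in covered
read bases and anti-monotone in total gap length.  The running best is a
per-read maximum updated in genome-streaming order (single pass), which
makes results deterministic given input order.

Survivors get a local affine-gap DP restricted to diagonals within
`band_pad` (default 10 bp) of the run's diagonal extent — enough to absorb
indels missed between sampled k-mers at the default sampling gaps.
Basepair scores default to +1/−2 with gap cost `2 + 1·len` (BLAST-like;
again, the method fixes none).  Alignment is local with soft-clipped read
ends reported as `S`.  Tie-breaking inside the DP is fixed and mirrored
by the test oracle: source preference M > D > I > fresh start, gap states
prefer opening, and the reported cell is the first maximal match cell in
scan order.  A band excluding every matrix cell raises an error, since it
can only arise from an internal inconsistency.  Alignments with
non-positive score yield no candidate.

Candidates are deduplicated across the 50%-overlapping windows on
(reference, position, strand), keeping the best score, and `select_best()`
keeps per read everything within `final_score_margin` (default 0) of the
best.  A read is *unique* when exactly one candidate survives.  MAPQ is
any monotone scheme by contract; here unique mappings get
`min(40, 1 + score gap to the runner-up)` with floor 1, non-unique get 0.

### Windows

Windows have length `2W`, stride `W`, so any alignment of length ≤ `W`
lies entirely in at least one window; `W` defaults to
`max(read_length, 500)`.  A sequence of length ≤ `2W` yields a single
window; otherwise windows start at every multiple of `W` below the
sequence end (the final ones truncated), and never span sequence
boundaries.

### Bisulfite mode

Bisulfite treatment converts unmethylated C to U (read as T), so read Ts
are ambiguous.  At indexing time every sampled read k-mer is expanded by
rewriting each T as either C or T (`2^#T` keys); reads are indexed forward
only, and instead both the forward and the reverse-complement strand of
each reference sequence are streamed.  Mappings found on the
reverse-complement stream are lifted back to forward coordinates with the
SAM reverse flag, the CIGAR reversed, and SEQ stored forward-oriented.
In the DP, read-T vs reference-C scores as a match and does not count in
`NM`.  K-mers with more than `expansion_cap` (default 10) Ts are skipped
entirely — unbounded expansion on T-rich reads is pathological, and a
read losing the rare all-T k-mer retains its other sampling offsets.

### Methylome utilities

*Monoclonal reads* are interpreted as mappings sharing an identical
(reference, 5′ start, strand) — the standard PCR-duplicate definition (the
source material does not define it); the highest-scoring one is kept,
then first-seen.  Methylation calling walks each mapping's CIGAR: at
reference Cs on the mapped strand, read C (G on the minus strand, since
SEQ is forward-oriented) is methylated evidence and read T (A) is
unmethylated; anything else is uninformative.  Calls require ≥ 5
informative reads by default and carry the strand-aware trinucleotide
context (CpG/CHG/CHH).

The agreement-ratio analysis takes eight counts — {inside, outside
regions} × {C/C, C/nonC genotype} × {difference, no difference} — and
reports, per stratum, the no-difference fraction at heterozygous sites
divided by that at homozygous sites.  Genotype classes are an *input*;
this package calls no SNPs.  The significance construction in the source
material is ambiguous; the committed layout is a 2×2 chi-square of
(region) × (agreement at C/nonC sites) with Yates correction when any
expected count is below 5, and the raw table is exposed so alternatives
can be tested.  With the published example counts this layout does not
produce a small p-value (only 11 informative heterozygous sites fall
inside the regions), so the tests assert the claimed ratio *inequality*,
not the p-value.

## The simulators: what they emulate, and what a green test means

* `simulate_wgs_reads()` draws uniform start positions and strands,
  mutates each template base with probability 0.1% (90% substitutions,
  10% indels of length uniform on 1–10, insertion and deletion
  equiprobable), then applies a 2% uniform sequencing error
  (substitution to a uniformly chosen different base).  These defaults
  are the stated simulation protocol of the benchmark this package
  mirrors; `fixed_indel_count`/`fixed_indel_range` additionally plant
  controlled indels for variant-tolerance experiments.
* `simulate_udcsd()` models a semi-repetitive genome: unique tags plus
  one ancestral tag copied `n_dup` times, the copies diverging at the
  coevolution rate `x`; the collection is then duplicated into species
  `r` and `s`, each tag diverging independently at rate `y`.  Both rates
  are i.i.d. substitutions only (the source describes them as mutation
  rates; indels are out of scope here), and all duplicates derive from a
  single ancestor.  The expected pairwise difference fraction between
  `r_i` and `s_i`, `2y(1−y) + (2/3)y²`, serves as a closed-form oracle.
* `simulate_bisulfite_reads()` draws reads from both strands and, per
  read and per CpG cytosine, methylates with probability
  `cpg_methylation_prob` (default 0.5, the stated protocol value);
  unmethylated CpG Cs and all non-CpG Cs convert to T.  Methylation
  states are independent across reads covering the same site — the
  simulator has no notion of a per-molecule epiallele.

Every simulator records a truth table whose edit tokens replay into the
exact read (`replay_read()`), and is bit-reproducible given its seed.

What the generators do **not** emulate: platform error profiles
(homopolymer errors, quality decay), non-uniform coverage, GC bias,
paired ends, real repeat structure beyond the UD-CSD caricature, SNPs
interacting with methylation, or partial bisulfite conversion.  A green
end-to-end test therefore establishes algorithmic correctness on the
stated stochastic world — uniform i.i.d. genomes and errors — not
performance claims on real libraries.  In particular, uniqueness on an
i.i.d. random genome is far easier than on a mammalian genome, and the
TPR = PPV = 1 recovery tests should be read as exactness checks of the
pipeline, not sensitivity claims.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; conversion to SAM's
  1-based `POS` happens only in `write_sam()`.
* `evaluate_mappings()` uses a 5-bp position tolerance by default (indels
  shift 5′ coordinates; the source states no tolerance); `Inf` disables
  the positional check for read-vs-read benchmarks such as UD-CSD.
* Empty match lists yield a null run of score 0; empty runs have
  skeleton 0; empty read or genome sets yield an empty result with a
  valid SAM header; reads shorter than the pattern span are flagged
  unmappable and emitted with SAM flag 4 rather than erroring.
* Scores are small integers represented in doubles throughout; the DP
  and its R oracle use identical tie-breaking, so score *and* CIGAR can
  be compared exactly.
* The presets scale the sampling gap with read length — high
  `ceiling(L/16)`, medium `ceiling(L/12)`, low/fast `ceiling(L/8)` —
  with kept fraction 0.99 (0.93 for fast).  The divisors interpolate the
  published setting of gap 12 for 200-bp reads at low sensitivity.

## Known limitations

Single-end only; SAM text only (no BAM/CRAM); no multithreading (the
contract is order-determinism); no quality-aware scoring; no SNP or CNV
calling; pattern optimization is out of scope (patterns are taken as
given).  The greedy chaining is a heuristic — it does not guarantee the
optimal chain, and the skeleton score is an estimate, not a proven bound,
so the two 3/4 filters can in principle discard the true locus of a read;
the acceptance-style tests quantify how often that happens in the stated
worlds (it does not happen for error-free reads, and remains ≥ 95% for
the variant-tolerance world).
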