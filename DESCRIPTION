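Package: poshmap
Title: Positional-Hashing Read Mapping with Gapped Patterns and Bisulfite Support
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A read mapper built on multi-positional hashing of gapped
    (spaced) k-mer patterns.  Reads are indexed in a single hash table keyed
    by gapped k-mers sampled at several offsets; the reference genome is
    streamed against the index in overlapping fixed-size windows.  Matching
    k-mers are chained into collinear runs by a greedy k-mer-level alignment
    with overlap-corrected match rewards, candidate runs are filtered by a
    skeleton (affine bound) score, and survivors are resolved by banded
    affine-gap dynamic programming into basepair alignments reported as SAM
    text.  Bisulfite-treated reads are supported through T/C k-mer-space
    expansion and asymmetric match scoring.  The package also ships read
    simulators (whole-genome shotgun with substitutions, indels and
    sequencing error; a unique/duplicated-coevolution-speciation-divergence
    benchmark; bisulfite conversion with per-CpG methylation), TPR/PPV
    evaluation against simulator truth, and downstream methylome utilities
    (monoclonal-read removal, coverage-thresholded methylation calling,
    agreement-ratio contingency analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
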