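Package: kmercn
Title: Mapping-Free, Paralog-Sensitive Copy-Number Estimation from Unique k-mers
Version: 0.1.0
Authors@R:
    person("kmercn", "developers", email = "kmercn@example.org", role = c("aut", "cre"))
Description: Estimates paralog-specific copy number from short-read sequencing
    data without read mapping. A catalog of k-mers that are unique in a
    reference genome and have few substitution near-matches is built once per
    reference; raw k-mer occurrence counts tabulated from a read stream are
    then corrected for local GC bias using counts at copy-number-invariant
    control regions and converted to windowed diploid copy-number tracks in
    BED format. Includes multi-sample summaries (per-sample MAD and outlier
    fractions, cross-sample window ranges, gene-level medians with male chrX
    handling), UCSC track-hub emission, and a deterministic simulator of toy
    references with diverged duplications, CNV genotypes, GC-biased reads and
    truth tracks used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
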