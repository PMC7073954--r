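---
title: "kmercn: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kmercn: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Diploid copy number from whole-genome sequencing is classically read from
mapped depth, but inside segmental duplications multi-mapping reads are
placed arbitrarily and depth loses its meaning per copy. `kmercn` sidesteps
alignment entirely. It precomputes, per reference genome, the set of k-mers
that are informative for depth: unique in the reference (a single exact
occurrence under canonical, strand-collapsed encoding) and not shadowed by
sequencing error — a k-mer with many near-identical neighbors elsewhere in
the genome would absorb erroneous copies of those neighbors' reads. In a
duplication family, the k-mers overlapping paralog-specific variants (PSVs)
are unique to one copy, so their sample counts genotype that copy alone.

## Pipeline stages and their parameters

### Catalog search (`kmer_search`)

* `k = 30` (≤ 32 so a k-mer packs into one 64-bit word at 2 bits/base).
  Larger k increases uniqueness but loses more k-mers to read errors, since
  a single error destroys all k windows that cross it.
* `edit_distance = 2`, `max_near = 100`: a candidate (exact count 1) is
  retained iff the total number of genome **occurrences** of all distinct
  canonical k-mers within substitution distance 1..2 is strictly less than
  100. "Occurrences" (a neighbor present five times contributes five) rather
  than distinct neighbor sequences is the deliberate reading: the risk being
  controlled is erroneous reads generated by neighbor loci, which scales
  with their copy number. Distance is substitution-only (Hamming): the
  neighborhood models base-calling errors, which do not shift frames.
* Variant enumeration is performed on the candidate's canonical form, each
  variant canonicalized before lookup and de-duplicated, so a variant and
  its reverse complement cannot be double-counted.
* `gc_window = 400` bp centered on the k-mer midpoint, clipped at
  chromosome ends, with unambiguous bases in the denominator. The GC
  context width is a convention (the depth-vs-GC effect in Illumina data is
  a fragment-scale phenomenon, so a few hundred bp); it is configurable and
  recorded in the index header.
* Control regions (BED, 0-based half-open) declare where copy number is
  assumed invariant across samples; `prepare_control()` builds the include
  file by merging exclusion tracks (segmental duplications, known CNVs,
  non-autosomes) and complementing against chromosome lengths. A k-mer is
  flagged control only when its full interval lies inside a control
  interval — partial overlap is ambiguous and is excluded.

### Counting (`count_kmers`)

Every window of every read, at step 1, is canonicalized and looked up;
catalog hits increment a per-record counter. Overlapping windows are the
point (each read of length L contributes L−k+1 draws); upstream read QC
(duplicates, secondary alignments) is delegated to the aligner toolchain
that feeds the stream. Worker partitioning merges per-worker tables, so
results are provably invariant to worker count and input splitting — the
reproducibility contract the tests enforce.

### Estimation (`estimate_cn`)

GC correction uses binned-mean factors (bin width 0.01 in GC fraction,
fitted on raw control counts, applied to all k-mers) rather than a smoothed
curve: it is the simplest model meeting the contract, deterministic, and
testable bin by bin. Bins with fewer than `min_control_per_bin = 100`
control k-mers inherit the nearest qualified bin's factor — with few
observations a ratio estimate is noisier than borrowing a neighbor, and GC
effects are smooth at the 0.01 scale. If no bin qualifies (toy genomes),
all non-empty bins are used, with a warning. The diploid baseline
`mu` is the mean corrected control count, computed after correction so the
two normalizations compose in stage order.

Windows hold exactly `window_kmers = 1000` consecutive catalog k-mers;
the window statistic is the mean (`median` available as an option), and
terminal sub-size groups are dropped by default so every emitted interval
summarizes the same number of k-mers. Windows never span chromosomes.

### Population layer

* Per-sample QC: unscaled MAD of window values (no 1.4826 consistency
  factor — it is a relative QC metric, and the constant would only rescale
  it) and the fraction of windows strictly outside [1.5, 2.5].
* Gene values: the median of windows overlapping the gene's longest isoform
  by at least 1 bp (ties on isoform span break to the smaller transcript
  id); genes with fewer than 3 windows are excluded — medians of one or two
  windows are dominated by window-boundary effects. Mitochondrial genes are
  excluded by chromosome-name filter.
* XY samples: genes entirely within chrX nonPAR are doubled before
  reporting (one X means the diploid scaling halves them); PAR genes are
  left alone; genes straddling a PAR boundary are flagged and left
  undoubled rather than silently mixing ploidy regimes. PAR coordinates are
  configuration (GRCh38 defaults shipped), since they are facts about a
  reference build, not about the method.
* Heatmap BED9 colors encode round-half-away-from-zero integers, saturating
  above 10; the track-hub writer emits hub/genomes/trackDb files that pass
  an offline stanza validator (unique track names, required keys).

## Numerical and representation choices

* A k-mer is a 64-bit value, 3' base in the least-significant bits; the
  per-base code is ASCII bits 1–2 (A=0, C=1, T=2, G=3), making reverse
  complementation per-slot subtraction of 2 mod 4 (an XOR) plus slot
  reversal. Canonical form is the smaller of the two encodings.
* R doubles cannot hold 64-bit integers exactly past 2^53 (k > 26), so the
  R-facing `encoded_kmer` carries the 8 bytes; `kmer_value()` refuses
  inexact conversion rather than silently rounding.
* The hash is classic multiplicative DJB2 (seed 5381, h×33+byte, 64-bit
  wraparound) over the value's 8 bytes most-significant first — the variant
  and byte order are pinned so hashes are bit-reproducible across builds.
* The table probes linearly from DJB2 mod capacity: upward from the lower
  half of the array, downward from the upper half, without wraparound;
  capacity is the next power of two at or above twice the key count (load
  factor ≤ 0.5). A probe that would run off an array edge triggers a
  transparent rebuild at doubled capacity.
* Ambiguity codes other than N are treated exactly like N: the k-mer is
  discarded. Soft-masked lowercase is uppercased (masking is annotation).
* Ties and degenerate inputs: empty reference → empty catalog; reads
  shorter than k count nothing; an empty control set or an all-zero control
  sample is a fatal configuration error rather than a silent NaN track.

## What the simulator emulates — and what it does not

`make_reference` draws i.i.d. bases at a target GC (default 0.41,
human-like); `implant_duplication` plants a copy with i.i.d. substitutions
at a chosen divergence (2% in the benchmark, typical of recent segmental
duplications and dense enough that ~45% of 30-mers in a copy overlap a
PSV); `apply_events` and `genotype_cohort` build diploid haplotypes with
deletions/tandem duplications and their per-base truth tracks;
`simulate_reads` draws uniform single-end reads (100 bp, 20x, 1% i.i.d.
substitution error) with optional sinusoidal GC-biased thinning
`(1 + a·sin(2πgc))/(1 + a)` — any smooth bias would do, the contract on
the estimator being only that correction flattens it.

Real data differ in ways the simulator deliberately ignores: non-uniform
insert-size and chimeric artifacts, error profiles that are neither i.i.d.
nor substitution-only, mappability and reference errors, population LD
between CNVs, and duplication divergence produced by phylogeny rather than
i.i.d. mutation. A green test therefore establishes algorithmic
correctness (encoding, filtering, counting, normalization, bookkeeping)
and statistical behavior under the stated noise model — not performance on
any particular real cohort.

One stated property required interpretation: "doubling read depth changes
window estimates by < 0.05 RMS" cannot hold between two *independent* read
draws at this window size (a 1000-k-mer window sees only ~200 independent
read stacks at 20x/100 bp, giving ~0.15 RMS sampling noise per draw); the
test feeds the same stream twice, which the depth normalization must cancel
exactly. Likewise, the uniqueness-filter oracle comparison uses half plain
random genomes and half genomes with implanted diverged duplications,
because a purely random 50 kb genome has no Hamming-2 neighbors at k = 30
and would test nothing.

## Known limitations

* k > 32 is unsupported by design (single-word encoding).
* The near-match search is exhaustive over the substitution neighborhood
  (~4005 variants per candidate at k=30, j=2); building a full human
  catalog is an hours-scale, multicore job, as expected for a
  once-per-reference step.
* No segmentation, breakpoint refinement or integer-genotype likelihoods:
  the output is the windowed copy-number track and its summaries.
* CRAM/BAM decoding is upstream (`samtools fasta -F 3840 | kmercn count`),
  keeping read QC policy out of the counter.
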