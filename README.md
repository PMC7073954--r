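# kmercn

Mapping-free, paralog-sensitive copy-number estimation from short-read
sequencing data.

## The problem

Read-depth CNV callers that rely on unique read mapping are blind inside
segmental duplications: reads from near-identical paralogs map ambiguously
and are placed at random, so the depth signal cannot say *which* copy of a
duplicated gene is gained or lost. `kmercn` takes the k-mer route instead.
A catalog of k-mers (default k = 30) that occur **exactly once** in the
reference and have **fewer than 100** genome occurrences of substitution
neighbors within edit distance 2 is built once per reference. Because a
k-mer overlapping a paralog-specific variant (PSV) is unique to one
duplicate copy, the sample depth observed at that k-mer measures the copy
number of that copy alone — no alignment required.

## The model

For catalog k-mer *i* with raw sample count `c_i`, local GC fraction `g_i`
(400 bp context) and the set `C` of control k-mers (those inside
user-supplied copy-number-invariant regions):

1. **GC correction** — control k-mers are binned by `g` (width 0.01);
   bin factor `f_b = mean(c_C) / mean(c_{C,b})`; corrected count
   `c'_i = c_i * f_{b(i)}`.
2. **Diploid scaling** — `cn_i = 2 * c'_i / mu`, with
   `mu = mean(c'_C)` the depth of the diploid state.
3. **Windowing** — consecutive catalog k-mers are grouped 1000 at a time
   per chromosome; the window value is their mean, written as 4-column BED.

Internals follow the field's k-mer-engine conventions: 2 bits per base
(ASCII bits 1–2: A=0, C=1, T=2, G=3, so complement = code − 2 mod 4), 3'
base in the least-significant bits, canonical form = min(value,
revcomp value), DJB2 hashing into an open-addressing table whose linear
probes run toward higher indices from the lower half of the array and
toward lower indices from the upper half.

## Worked example

Everything below is simulated — no downloads. A 505 kb diploid genome
carries a 5 kb duplication at 2% divergence (paralogs at 100–105 kb and
400–405 kb), a hemizygous deletion (truth 1), a homozygous tandem
duplication (truth 4), and a hemizygous deletion of the second paralog copy
(truth 1 for that copy, 2 for its partner), sequenced at 20x with 1% error:

```r
library(kmercn)
bm      <- simulate_cnv_benchmark(seed = 7)
catalog <- kmer_search(bm$reference, control = bm$control,
                       k = 30, edit_distance = 2, max_near = 100)
counts  <- count_kmers(catalog, bm$reads, raw_sequences = TRUE)
track   <- estimate_cn(catalog, counts, window_kmers = 1000)
for (rn in names(bm$regions)) {
  r  <- bm$regions[[rn]]
  ix <- track$start >= r[1] & track$end <= r[2]
  cat(sprintf("%-24s %d windows, mean cn %.3f\n", rn, sum(ix), mean(track$cn[ix])))
}
```

Output from this exact script:

```
hemizygous_deletion      4 windows, mean cn 1.028
homozygous_duplication   4 windows, mean cn 4.035
paralog_deleted          1 windows, mean cn 0.997
paralog_partner          2 windows, mean cn 2.154
```

The deleted paralog copy reads ~1 while its partner stays ~2 — the
paralog-specific resolution that mapping-based depth callers cannot give
(the partner's 2.154 is local read-sampling noise at 20x; its regional mean
still rounds to 2). `write_track_bed(track, "sample.cn.bed")` emits the
browser track; `heatmap_bed()`, `gene_cn_matrix()`, `sample_mad()`,
`window_ranges()` and `build_trackhub()` cover multi-sample summaries.

A command-line interface mirrors the pipeline (installed at
`exec/kmercn`):

```sh
kmercn search ref.fa --control include.bed -k 30 -e 2 --max-near 100 -o ref.kdx
samtools fasta -F 3840 sample.cram | kmercn count ref.kdx -o sample.counts
kmercn est ref.kdx sample.counts -o sample.cn.bed -w 1000
```

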