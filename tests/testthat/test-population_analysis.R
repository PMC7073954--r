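# Multi-sample summaries, gene-level copy number and track emission.

mk_track <- function(cn, chrom = "chr1", width = 1000L,
                     start = seq(0L, by = width, length.out = length(cn))) {
  chrom <- rep_len(chrom, length(cn))
  structure(data.frame(chrom = chrom, start = start, end = start + width,
                       cn = cn, n_kmers = rep(1000L, length(cn)),
                       stringsAsFactors = FALSE),
            class = c("cn_track", "data.frame"))
}

test_that("MAD is the unscaled median absolute deviation", {
  expect_equal(sample_mad(mk_track(c(1.8, 2.0, 2.2, 2.0, 2.4))), 0.2)
  expect_equal(sample_mad(mk_track(rep(2.37, 9))), 0)
  expect_equal(sample_mad(mk_track(2.1)), 0)
  expect_error(sample_mad(mk_track(numeric(0))), "empty")
  # translation invariance and linear dilation
  set.seed(71)
  x <- runif(101, 0, 4)
  expect_equal(sample_mad(mk_track(x + 3)), sample_mad(mk_track(x)))
  expect_equal(sample_mad(mk_track(3 * x)), 3 * sample_mad(mk_track(x)))
  # no 1.4826 consistency factor
  expect_equal(sample_mad(mk_track(x)),
               stats::mad(x, constant = 1))
})

test_that("outlier fraction uses exclusive 1.5/2.5 boundaries", {
  expect_equal(outlier_fraction(mk_track(rep(2, 10))), 0)
  expect_equal(outlier_fraction(mk_track(c(1.0, 2.0, 3.0, 2.0))), 0.5)
  expect_equal(outlier_fraction(mk_track(c(1.5, 2.5))), 0)
  expect_equal(outlier_fraction(mk_track(c(1.4999, 2.5001))), 1)
  expect_error(outlier_fraction(mk_track(numeric(0))), "empty")
})

test_that("window ranges across samples; coordinate mismatch is an error", {
  tr <- list(a = mk_track(c(1.0, 2.0, 2.0)),
             b = mk_track(c(2.0, 2.0, 2.0)),
             c = mk_track(c(4.0, 2.0, 2.0)))
  wr <- window_ranges(tr)
  expect_equal(wr$range, c(3, 0, 0))
  expect_equal(wr$min, c(1, 2, 2))
  expect_equal(wr$max, c(4, 2, 2))
  expect_equal(wr$mean[1], 7 / 3, tolerance = 1e-12)
  expect_true(all(wr$min <= wr$mean & wr$mean <= wr$max))
  # single sample: range 0 everywhere
  expect_true(all(window_ranges(tr[1])$range == 0))
  # identical tracks: range 0
  expect_true(all(window_ranges(list(tr$a, tr$a))$range == 0))
  bad <- mk_track(c(2, 2, 2), start = c(0L, 1000L, 2500L))
  expect_error(window_ranges(list(tr$a, bad)), "coordinates differ")
  # naive per-window scan agreement on random cohorts
  set.seed(72)
  cohort <- lapply(1:5, function(i) mk_track(runif(20, 0, 5)))
  wr2 <- window_ranges(cohort)
  m <- sapply(cohort, function(t) t$cn)
  expect_equal(wr2$min, apply(m, 1, min))
  expect_equal(wr2$max, apply(m, 1, max))
})

test_that("longest isoform selected per gene, ties to smaller transcript id", {
  models <- data.frame(
    chrom = "chr1",
    start = c(0, 0, 100, 500, 500),
    end = c(1000, 2500, 600, 900, 900),
    gene = c("G1", "G1", "G2", "G3", "G3"),
    transcript = c("t2", "t1", "t9", "tB", "tA"), stringsAsFactors = FALSE)
  iso <- select_longest_isoform(models)
  expect_equal(nrow(iso), 3)
  expect_equal(iso$transcript[iso$gene == "G1"], "t1")  # span 2500 wins
  expect_equal(iso$transcript[iso$gene == "G2"], "t9")  # single isoform
  expect_equal(iso$transcript[iso$gene == "G3"], "tA")  # tie: smaller id
})

test_that("gene copy number: median of intersecting windows, >=3 required", {
  track <- mk_track(c(1.9, 2.1, 3.0, 2.0, 2.0))
  g <- data.frame(chrom = "chr1", start = 100, end = 2900)  # windows 1-3
  expect_equal(as.numeric(gene_copy_number(g, track)), 2.1)
  g2 <- data.frame(chrom = "chr1", start = 100, end = 1900) # 2 windows
  out <- gene_copy_number(g2, track)
  expect_true(is.na(out))
  expect_true(attr(out, "excluded"))
  # >= 1 bp overlap counts: end exactly at window start does not
  g3 <- data.frame(chrom = "chr1", start = 0, end = 2001)   # 3rd window by 1bp
  expect_equal(attr(gene_copy_number(g3, track), "n_windows"), 3L)
  # brute-force agreement on random genes
  set.seed(73)
  track2 <- mk_track(runif(50, 0, 5))
  for (i in 1:100) {
    s <- sample(0:48000, 1); e <- s + sample(500:20000, 1)
    gi <- data.frame(chrom = "chr1", start = s, end = e)
    ix <- which(track2$start < e & track2$end > s)
    want <- if (length(ix) < 3) NA_real_ else median(track2$cn[ix])
    expect_equal(as.numeric(gene_copy_number(gi, track2)), want)
  }
})

test_that("male chrX nonPAR doubling is applied exactly once", {
  par <- par_regions_grch38()
  xtrack <- mk_track(rep(1.0, 2000), chrom = "chrX", width = 100000L)
  nonpar_gene <- data.frame(chrom = "chrX", start = 5e6, end = 5.6e6)
  par_gene <- data.frame(chrom = "chrX", start = 100000, end = 700000)
  strad_gene <- data.frame(chrom = "chrX", start = 2500000, end = 3200000)
  auto_gene <- data.frame(chrom = "chr1", start = 5e6, end = 5.6e6)
  # XY: nonPAR doubled, PAR untouched, straddler flagged and undoubled
  expect_equal(as.numeric(gene_copy_number(nonpar_gene, xtrack, sex = "XY")), 2)
  expect_equal(as.numeric(gene_copy_number(par_gene, xtrack, sex = "XY")), 1)
  strad <- gene_copy_number(strad_gene, xtrack, sex = "XY")
  expect_equal(as.numeric(strad), 1)
  expect_true(attr(strad, "par_boundary"))
  # XX: never doubled
  expect_equal(as.numeric(gene_copy_number(nonpar_gene, xtrack, sex = "XX")), 1)
  # autosomes never doubled for anyone
  atrack <- mk_track(rep(1.0, 2000), chrom = "chr1", width = 100000L)
  expect_equal(as.numeric(gene_copy_number(auto_gene, atrack, sex = "XY")), 1)
})

test_that("gene matrix drops chrM and applies per-sample sex", {
  models <- data.frame(
    chrom = c("chr1", "chrX", "chrM"),
    start = c(100, 5e6, 0), end = c(350000, 5.6e6, 16000),
    gene = c("A1", "XG", "MT1"),
    transcript = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
  tr1 <- rbind(mk_track(rep(2, 10), chrom = "chr1", width = 100000L),
               mk_track(rep(1, 100), chrom = "chrX", width = 100000L))
  tr1 <- structure(tr1, class = c("cn_track", "data.frame"))
  tracks <- list(male = tr1, female = tr1)
  res <- gene_cn_matrix(models, tracks,
                        sex = c(male = "XY", female = "XX"))
  expect_equal(sort(rownames(res$cn)), c("A1", "XG"))
  expect_equal(res$cn["XG", "male"], 2)    # doubled
  expect_equal(res$cn["XG", "female"], 1)
  expect_equal(res$cn["A1", "male"], 2)
})

test_that("heatmap colors encode half-away-from-zero rounding", {
  track <- mk_track(c(2.4, 2.5, 0.0, 0.49, 10.4, 12.0))
  hb <- heatmap_bed(track)
  pal <- cn_palette()
  expect_equal(hb$itemRgb,
               unname(pal[c("2", "3", "0", "0", "10", ">10")]))
  expect_equal(ncol(hb), 9)
  expect_equal(hb$thickStart, track$start)
  p <- tempfile(fileext = ".bed")
  heatmap_bed(track, p)
  expect_equal(length(readLines(p)), nrow(track))
})

test_that("track hub emission passes offline validation", {
  d <- tempfile("hub")
  samples <- data.frame(sample = c("s1", "s2"),
                        population = c("AFR", "EUR"),
                        raw_bed = c("s1.bed", "s2.bed"),
                        heatmap_bed = c("s1.heat.bed", "s2.heat.bed"),
                        stringsAsFactors = FALSE)
  build_trackhub(samples, d, genome = "hg38")
  expect_true(validate_trackhub(d))
  tdb <- readLines(file.path(d, "hg38", "trackDb.txt"))
  expect_equal(sum(startsWith(tdb, "track ")), 4)  # raw + heatmap per sample
  expect_equal(sum(grepl("^group AFR$", tdb)), 2)
  # empty sample set: valid empty hub
  d2 <- tempfile("hub")
  build_trackhub(samples[0, ], d2)
  expect_true(validate_trackhub(d2))
  # duplicate sample names rejected
  expect_error(build_trackhub(rbind(samples, samples[1, ]), tempfile()),
               "duplicate")
})
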