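# Catalog construction: enumeration, uniqueness, near-match filter, GC and
# control annotation, serialization.

test_that("enumeration counts canonical windows; N discards; short is empty", {
  occ <- enumerate_occurrences(c(g = "ACGTACGT"), k = 4)
  df <- as.data.frame(occ)
  got <- setNames(df$count, df$kmer)
  expect_equal(got[["ACGT"]], 2)   # self-reverse-complementary, two windows
  expect_equal(got[["CGTA"]], 2)   # CGTA and TACG are mutual revcomps
  expect_equal(got[["GTAC"]], 1)
  expect_equal(sum(df$count), 5)
  expect_equal(length(enumerate_occurrences(c(g = "ACNGT"), 4)$counts), 0)
  expect_equal(length(enumerate_occurrences(c(g = "ACG"), 4)$counts), 0)
  # oracle agreement on random multi-sequence genomes
  set.seed(5)
  for (i in 1:5) {
    seqs <- setNames(vapply(1:2, function(j) paste(
      sample(c("A", "C", "G", "T", "N"), 300, TRUE,
             prob = c(.24, .24, .24, .24, .04)), collapse = ""), ""),
      c("c1", "c2"))
    occ <- enumerate_occurrences(seqs, k = 6)
    df <- as.data.frame(occ)
    oracle <- enumerate_oracle(seqs, 6)
    expect_equal(sort(names(oracle)), sort(df$kmer))
    expect_equal(unname(oracle[df$kmer]), df$count, ignore_attr = TRUE)
  }
})

test_that("candidates are exactly the count-1 k-mers", {
  occ <- enumerate_occurrences(c(g = "ACGTACGT"), k = 4)
  expect_equal(as.character(select_candidates(occ)), "GTAC")
  occ2 <- enumerate_occurrences(c(g = "AAAAAAA"), k = 4)     # AAAA x4
  expect_equal(length(select_candidates(occ2)), 0)
})

test_that("near-match counts agree with the string oracle; j=0 is empty", {
  occ <- enumerate_occurrences(c(g = "ACGTACGT"), k = 4)
  cand <- select_candidates(occ)
  expect_equal(near_match_count(cand, occ, j = 0), 0)
  expect_equal(near_match_count(cand, occ, j = 2), 0)
  # random tiny genomes: neighborhood-enumeration vs quadratic string scan
  set.seed(11)
  for (i in 1:5) {
    g <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    occ <- enumerate_occurrences(c(g = g), k = 5)
    cand <- select_candidates(occ)
    occ_tab <- as.data.frame(occ)
    occ_lookup <- setNames(occ_tab$count, occ_tab$kmer)
    for (j in 1:2) {
      got <- near_match_count(cand, occ, j = j)
      want <- vapply(as.character(cand), function(s)
        near_oracle_str(s, occ_lookup, j), 0, USE.NAMES = FALSE)
      expect_equal(got, want, info = sprintf("seed-rep %d j %d", i, j))
    }
  }
})

test_that("a planted Hamming-1 neighborhood is counted occurrence-wise", {
  # genome holds the candidate once plus a 1-substitution neighbor 3 times;
  # separators of N prevent bridging windows
  cand <- "ACGGATTACC"
  nb <- "ACGGATTACA"                 # Hamming distance 1
  g <- paste(c(cand, "N", nb, "N", nb, "N", nb), collapse = "")
  occ <- enumerate_occurrences(c(g = g), k = 10)
  cs <- new_set <- as.character(select_candidates(occ))
  expect_true(canon_str(cand) %in% cs)
  got <- near_match_count(canon_str(cand), occ, j = 1)
  expect_equal(got, 3)               # occurrences, not distinct neighbors
  expect_equal(near_match_count(canon_str(cand), occ, j = 2), 3)
})

test_that("filter retains strictly below max_near", {
  # plant exactly 100 single-substitution neighbor occurrences
  cand <- "ACGGATTACCGATCGA"
  nb <- sub("^A", "C", cand)
  g100 <- paste(c(cand, rep(c("N", nb), 100)), collapse = "")
  occ <- enumerate_occurrences(c(g = g100), k = nchar(cand))
  cands <- select_candidates(occ)
  stopifnot(canon_str(cand) %in% as.character(cands))
  kept100 <- filter_catalog(cands, occ, max_near = 100, j = 1)
  expect_false(canon_str(cand) %in% as.character(kept100))  # 100 is too many
  kept101 <- filter_catalog(cands, occ, max_near = 101, j = 1)
  expect_true(canon_str(cand) %in% as.character(kept101))   # 100 < 101
  # monotonicity: raising max_near never shrinks; raising j never grows
  expect_true(all(as.character(kept100) %in% as.character(kept101)))
  k_j1 <- filter_catalog(cands, occ, max_near = 100, j = 1)
  k_j2 <- filter_catalog(cands, occ, max_near = 100, j = 2)
  expect_true(all(as.character(k_j2) %in% as.character(k_j1)))
})

test_that("perfect duplication removes inside k-mers; divergence rescues", {
  k <- 20
  base <- make_reference(3000, seed = 21, name = "c1")
  # verbatim duplication: every k-mer fully inside either copy leaves
  dup0 <- implant_duplication(base, "c1", 500, 800, insert_at = 2000,
                              divergence = 0, seed = 1)
  cat0 <- kmer_search(dup0$reference, k = k, edit_distance = 2,
                      max_near = 100)
  inside0 <- cat0$start >= 500 & cat0$start + k <= 800
  expect_equal(sum(inside0), 0)
  inside_copy0 <- cat0$start >= 2000 & cat0$start + k <= 2300
  expect_equal(sum(inside_copy0), 0)
  # diverged duplication: k-mers overlapping a substitution re-enter
  dup1 <- implant_duplication(base, "c1", 500, 800, insert_at = 2000,
                              divergence = 0.03, seed = 2)
  expect_gt(length(dup1$mutated), 0)
  cat1 <- kmer_search(dup1$reference, k = k, edit_distance = 2,
                      max_near = 100)
  psv <- dup1$mutated[1]             # position in the inserted copy
  src_psv <- psv - 2000 + 500        # mirrored position in the source
  over_copy <- cat1$start <= psv & cat1$start + k > psv &
    cat1$start >= 2000 & cat1$start + k <= 2300
  over_src <- cat1$start <= src_psv & cat1$start + k > src_psv &
    cat1$start >= 500 & cat1$start + k <= 800
  expect_gt(sum(over_copy), 0)       # paralog-specific k-mers, copy side
  expect_gt(sum(over_src), 0)        # and source side
})

test_that("catalog equals the brute-force oracle on a small genome", {
  ref <- make_reference(8000, seed = 31, name = "c1")
  dup <- implant_duplication(ref, "c1", 1000, 1600, insert_at = 5000,
                             divergence = 0.02, seed = 32)
  occ <- enumerate_occurrences(dup$reference, k = 30)
  cand <- select_candidates(occ)
  for (j in 1:2) {
    got <- near_match_count(cand, occ, j = j)
    om <- kmercn:::cpp_hamming_oracle(occ$values, occ$counts, cand$values, 30L)
    expect_identical(got, om[, j])
  }
})

test_that("annotation: position, control containment, GC context", {
  set.seed(17)
  gc_block <- paste(sample(c("G", "C"), 200, TRUE), collapse = "")
  at_block <- paste(sample(c("A", "T"), 200, TRUE), collapse = "")
  g <- paste0(gc_block, at_block)
  k <- 15
  ctrl <- data.frame(chrom = "c1", start = 0, end = 100)
  cat1 <- kmer_search(c(c1 = g), control = ctrl, k = k, gc_window = 20)
  df <- as.data.frame(cat1)
  expect_gt(nrow(df), 100)
  expect_equal(df$kmer, vapply(df$start, function(s)
    canon_str(substr(g, s + 1, s + k)), ""))
  expect_true(all(diff(df$start) > 0))                # chromosomal order
  # control flag: [start, start+k) within [0, 100) only
  expect_equal(df$is_control, df$start + k <= 100)
  # straddling k-mers (partially inside) are not control
  strad <- df$start < 100 & df$start + k > 100
  expect_true(all(!df$is_control[strad]))
  # 20 bp context wholly inside the G/C block -> gc_fraction exactly 1;
  # wholly inside the A/T block -> exactly 0
  deep_gc <- df$start + k / 2 >= 10 & df$start + k / 2 <= 190
  expect_true(all(abs(df$gc[deep_gc] - 1) < 1e-12))
  deep_at <- df$start + k / 2 >= 210 & df$start + k / 2 <= 390
  expect_true(all(abs(df$gc[deep_at]) < 1e-12))
})

test_that("whole-chromosome control marks every record", {
  ref <- make_reference(2000, seed = 4, name = "c1")
  ctrl <- data.frame(chrom = "c1", start = 0, end = 2000)
  cat1 <- kmer_search(ref, control = ctrl, k = 15)
  expect_true(all(cat1$is_control))
  cat2 <- kmer_search(ref, control = NULL, k = 15)
  expect_true(all(!cat2$is_control))
})

test_that("thread invariance of the catalog", {
  ref <- make_reference(20000, seed = 8, name = "c1")
  dup <- implant_duplication(ref, "c1", 2000, 3000, insert_at = 15000,
                             divergence = 0.05, seed = 9)
  c1 <- kmer_search(dup$reference, k = 30, threads = 1)
  c4 <- kmer_search(dup$reference, k = 30, threads = 4)
  expect_identical(c1$values, c4$values)
  expect_identical(c1$start, c4$start)
})

test_that("index serialization round-trips bit-exactly with guards", {
  ref <- make_reference(1500, seed = 12, name = "chrZ")
  ctrl <- data.frame(chrom = "chrZ", start = 100, end = 900)
  cat1 <- kmer_search(ref, control = ctrl, k = 21)
  path <- tempfile(fileext = ".kdx")
  write_index(cat1, path)
  back <- read_index(path)
  expect_identical(unclass(back), unclass(cat1))
  # parameter mismatch
  expect_error(read_index(path, k = 30), class = "kmercn_format_error")
  # truncation
  trunc <- tempfile()
  bytes <- readBin(path, raw(), file.size(path))
  writeBin(bytes[1:(length(bytes) - 50)], trunc)
  expect_error(read_index(trunc), class = "kmercn_format_error")
  # wrong magic
  junk <- tempfile()
  writeBin(charToRaw("NOTANIDX"), junk)
  expect_error(read_index(junk), class = "kmercn_format_error")
})

test_that("prepare-control merges exclusions and complements lengths", {
  genome <- c(c1 = 1000L, c2 = 500L)
  excl <- data.frame(chrom = c("c1", "c1", "c2"),
                     start = c(100, 150, 0), end = c(200, 300, 500))
  inc <- prepare_control(genome, excl)
  expect_equal(inc$chrom, c("c1", "c1"))      # c2 fully excluded
  expect_equal(inc$start, c(0, 300))
  expect_equal(inc$end, c(100, 1000))
  # no exclusions: whole genome included
  all_in <- prepare_control(genome)
  expect_equal(all_in$end - all_in$start, unname(genome))
})
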