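# Independent reference implementations used as oracles. These deliberately
# share no code with the package's hash/bit paths: strings, match() and
# arithmetic only (Biostrings is used solely to reverse-complement strings).

revcomp_str <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

# numeric value of the 2-bit encoding, exact for k <= 26 (string arithmetic)
enc_val_str <- function(s) {
  code <- c(A = 0, C = 1, T = 2, G = 3)
  vapply(s, function(x) {
    v <- 0
    for (ch in strsplit(x, "")[[1]]) v <- v * 4 + code[[ch]]
    v
  }, 0, USE.NAMES = FALSE)
}

# canonical form by encoded-value order (not lexicographic!)
canon_str <- function(s) {
  rc <- revcomp_str(s)
  ifelse(enc_val_str(rc) < enc_val_str(s), rc, s)
}

# all k-mer windows of a sequence, NA-free only
windows_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  w[!grepl("[^ACGT]", w)]
}

# enumeration oracle: canonical k-mer -> occurrence count, for tiny genomes
enumerate_oracle <- function(seqs, k) {
  w <- unlist(lapply(unname(seqs), windows_of, k = k))
  if (length(w) == 0) return(integer(0))
  table(canon_str(w))
}

# naive dictionary counter: occurrences of catalog k-mers (either strand) in
# reads; entry-for-entry comparable with count_kmers()
naive_count_oracle <- function(catalog_kmers, reads, k) {
  win <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) character(0) else substring(r, 1:(n - k + 1), k:n)
  }))
  if (length(win) == 0) return(rep(0, length(catalog_kmers)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(win)))
  i1 <- match(win, catalog_kmers)
  i2 <- match(rc, catalog_kmers)
  hit <- ifelse(is.na(i1), i2, i1)
  tabulate(hit[!is.na(hit)], nbins = length(catalog_kmers))
}

# quadratic near-match oracle in plain R strings, for tiny genomes:
# sum of genome occurrence counts of distinct canonical k-mers at
# strand-minimized Hamming distance 1..j from the candidate
hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

near_oracle_str <- function(cand, occ_table, j) {
  genome <- names(occ_table)
  rc <- revcomp_str(genome)
  total <- 0
  for (i in seq_along(genome)) {
    if (genome[i] == cand) next
    d <- min(hamming_str(cand, genome[i]), hamming_str(cand, rc[i]))
    if (d >= 1 && d <= j) total <- total + occ_table[[i]]
  }
  total
}

# convenience: catalog build on an in-memory genome
tiny_catalog <- function(seqs, k, control = NULL, ...) {
  kmer_search(seqs, control = control, k = k, ...)
}
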