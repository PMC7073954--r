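# Deterministic simulator: toy references, diverged duplications, CNV
# genotypes, GC-biased reads and per-base truth tracks. This is the
# download-free test surface for the whole pipeline; every function is
# reproducible given its seed (seeds are applied in a local RNG scope).

BASES <- c("A", "C", "G", "T")

#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2, so realized GC
#' concentrates at `gc` (within ~2 points for length >= 10 kb).
#'
#' @param length Sequence length in bp.
#' @param gc Target GC fraction (default 0.41, the human-like value).
#' @param seed RNG seed; identical seeds give identical sequences.
#' @param name Sequence name.
#' @return Named character vector of length 1.
#' @export
make_reference <- function(length, gc = 0.41, seed = 1L, name = "chrS") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  withr::with_seed(seed, {
    b <- sample(BASES, length, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    setNames(paste(b, collapse = ""), name)
  })
}

#' Write sequences as FASTA
#' @param seqs Named character vector (or `DNAStringSet`).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

mutate_bases <- function(ch) {
  # substitute each base by one of the three others, uniformly
  BASES[(match(ch, BASES) - 1L + sample.int(3L, length(ch), replace = TRUE)) %% 4L + 1L]
}

#' Implant a (possibly diverged) duplication into a reference
#'
#' Copies the source interval, applies i.i.d. substitutions at the given
#' per-base divergence (these are the paralog-specific variants), and
#' inserts the copy at `insert_at`. With divergence 0 the copies are
#' byte-identical, so every k-mer wholly inside either copy acquires exact
#' count 2 and leaves the catalog; each substitution rescues the k-mers
#' overlapping it in both copies.
#'
#' @param reference Named character vector (or FASTA path/`DNAStringSet`).
#' @param chrom Sequence name holding the source.
#' @param start,end Source interval, 0-based half-open.
#' @param insert_at Insertion point (0-based, outside the source interval).
#' @param divergence Per-base substitution probability for the inserted copy.
#' @param seed RNG seed.
#' @return List: `reference` (modified), `copy_interval` (0-based half-open
#'   interval of the inserted copy in the new coordinates), `source_interval`
#'   (source in new coordinates), `mutated` (0-based positions of the
#'   substitutions within the new coordinates).
#' @export
implant_duplication <- function(reference, chrom, start, end, insert_at,
                                divergence = 0, seed = 1L) {
  seqs <- load_reference(reference)
  stopifnot(chrom %in% names(seqs), start >= 0, end > start,
            end <= nchar(seqs[[chrom]]), divergence >= 0, divergence <= 1)
  if (insert_at > start && insert_at < end)
    stop("insertion point lies inside the source interval")
  s <- seqs[[chrom]]
  copy <- substr(s, start + 1L, end)
  len <- end - start
  mut_local <- integer(0)
  withr::with_seed(seed, {
    hit <- which(runif(len) < divergence)
    if (length(hit)) {
      ch <- strsplit(copy, "")[[1]]
      ch[hit] <- mutate_bases(ch[hit])
      copy <- paste(ch, collapse = "")
      mut_local <- hit - 1L
    }
  })
  seqs[[chrom]] <- paste0(substr(s, 1L, insert_at), copy,
                          substr(s, insert_at + 1L, nchar(s)))
  shift <- function(p) ifelse(p >= insert_at, p + len, p)
  list(reference = seqs,
       copy_interval = c(insert_at, insert_at + len),
       source_interval = c(shift(start), shift(start) + len),
       mutated = insert_at + mut_local)
}

#' Apply deletion/duplication events to one haplotype
#'
#' Events are intervals in reference coordinates; deletions remove the
#' interval, duplications insert a tandem copy immediately after it.
#' Events on one chromosome must not overlap.
#'
#' @param reference Named character vector (or FASTA path/`DNAStringSet`).
#' @param events data.frame(chrom, start, end, type) with type
#'   `"deletion"` or `"duplication"`.
#' @return Named character vector: the haplotype sequence(s).
#' @export
apply_events <- function(reference, events) {
  seqs <- load_reference(reference)
  if (is.null(events) || nrow(events) == 0) return(seqs)
  stopifnot(all(events$type %in% c("deletion", "duplication")))
  for (chr in unique(events$chrom)) {
    ev <- events[events$chrom == chr, , drop = FALSE]
    ev <- ev[order(-ev$start), , drop = FALSE]  # right-to-left keeps coords valid
    s <- seqs[[chr]]
    for (i in seq_len(nrow(ev))) {
      seg <- substr(s, ev$start[i] + 1L, ev$end[i])
      s <- if (ev$type[i] == "deletion")
        paste0(substr(s, 1L, ev$start[i]), substr(s, ev$end[i] + 1L, nchar(s)))
      else
        paste0(substr(s, 1L, ev$end[i]), seg, substr(s, ev$end[i] + 1L, nchar(s)))
    }
    seqs[[chr]] <- s
  }
  seqs
}

#' Per-base truth copy-number track for a diploid individual
#'
#' Truth at any reference base is 2 plus copies gained minus copies lost,
#' summed over the two haplotypes' events.
#'
#' @param seqlengths Named vector of reference sequence lengths.
#' @param events_h1,events_h2 Event data.frames (see [apply_events()]).
#' @return data.frame(chrom, start, end, cn): piecewise-constant, adjacent
#'   equal-cn segments merged, partitioning every sequence.
#' @export
truth_track <- function(seqlengths, events_h1 = NULL, events_h2 = NULL) {
  evs <- rbind(if (!is.null(events_h1) && nrow(events_h1))
                 cbind(events_h1, hap = 1L),
               if (!is.null(events_h2) && nrow(events_h2))
                 cbind(events_h2, hap = 2L))
  out <- lapply(names(seqlengths), function(chr) {
    len <- unname(seqlengths[[chr]])
    e <- if (is.null(evs)) NULL else evs[evs$chrom == chr, , drop = FALSE]
    bnd <- sort(unique(c(0L, len, if (!is.null(e)) c(e$start, e$end))))
    bnd <- bnd[bnd >= 0 & bnd <= len]
    st <- head(bnd, -1L); en <- bnd[-1L]
    cn <- rep(2L, length(st))
    if (!is.null(e) && nrow(e)) {
      for (i in seq_len(nrow(e))) {
        cov <- st >= e$start[i] & en <= e$end[i]
        cn[cov] <- cn[cov] + if (e$type[i] == "duplication") 1L else -1L
      }
    }
    run <- rle(cn)
    stops <- cumsum(run$lengths)
    data.frame(chrom = chr, start = st[c(1L, head(stops, -1L) + 1L)],
               end = en[stops], cn = run$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Draw diploid CNV genotypes for a cohort
#'
#' Each locus is carried independently per haplotype with its allele
#' frequency; the per-individual truth track follows from the drawn events.
#'
#' @param loci data.frame(chrom, start, end, type, freq).
#' @param n_individuals Cohort size.
#' @param seqlengths Named reference lengths (for the truth tracks).
#' @param seed RNG seed.
#' @return List of individuals, each
#'   `list(id, events = list(h1, h2), truth)`.
#' @export
genotype_cohort <- function(loci, n_individuals, seqlengths, seed = 1L) {
  stopifnot(all(loci$freq >= 0), all(loci$freq <= 1))
  withr::with_seed(seed, {
    lapply(seq_len(n_individuals), function(i) {
      carry <- matrix(runif(2L * nrow(loci)) < loci$freq, ncol = 2L)
      ev <- function(h) loci[carry[, h], c("chrom", "start", "end", "type"),
                             drop = FALSE]
      list(id = sprintf("sim%03d", i),
           events = list(h1 = ev(1L), h2 = ev(2L)),
           truth = truth_track(seqlengths, ev(1L), ev(2L)))
    })
  })
}

#' Simulate GC-biased single-end reads from haplotype sequences
#'
#' Read starts are uniform, then thinned by the acceptance probability
#' `(1 + gc_bias * sin(2*pi*gc)) / (1 + gc_bias)` of each fragment's GC
#' fraction (identically 1 when `gc_bias = 0`); strands are equiprobable and
#' substitution errors i.i.d. at `error_rate`. Total depth is divided evenly
#' among the supplied haplotypes, so two haplotypes at `depth = 20` give the
#' 20x diploid genome the defaults describe.
#'
#' @param haplotypes Character vector (or list) of haplotype sequences.
#' @param depth Combined mean sequencing depth (default 20).
#' @param read_length Read length in bp (default 100).
#' @param error_rate Per-base substitution error rate (default 0.01).
#' @param gc_bias Bias amplitude in `[0, 1)`; 0 disables thinning.
#' @param seed RNG seed.
#' @return Character vector of read sequences.
#' @export
simulate_reads <- function(haplotypes, depth = 20, read_length = 100L,
                           error_rate = 0.01, gc_bias = 0, seed = 1L) {
  haps <- unname(unlist(lapply(haplotypes, as.character)))
  stopifnot(depth > 0, error_rate >= 0, error_rate < 1,
            gc_bias >= 0, gc_bias < 1)
  withr::with_seed(seed, {
    reads <- character(0)
    for (h in haps) {
      len <- nchar(h)
      if (len < read_length) next
      n_target <- round((depth / length(haps)) * len / read_length)
      if (gc_bias > 0) {
        # pilot-estimate mean acceptance so realized depth matches depth
        pil <- sample.int(len - read_length + 1L, min(2000L, n_target),
                          replace = TRUE)
        p_hat <- mean(accept_prob(substring(h, pil, pil + read_length - 1L),
                                  gc_bias))
        n_cand <- ceiling(n_target / max(p_hat, 1e-3))
      } else n_cand <- n_target
      starts <- sample.int(len - read_length + 1L, n_cand, replace = TRUE)
      frag <- substring(h, starts, starts + read_length - 1L)
      if (gc_bias > 0)
        frag <- frag[runif(n_cand) < accept_prob(frag, gc_bias)]
      reads <- c(reads, frag)
    }
    if (length(reads)) {
      flip <- runif(length(reads)) < 0.5
      if (any(flip))
        reads[flip] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(reads[flip])))
      if (error_rate > 0) {
        n_err <- rbinom(length(reads), nchar(reads), error_rate)
        for (i in which(n_err > 0)) {
          ch <- strsplit(reads[i], "")[[1]]
          pos <- sample.int(length(ch), n_err[i])
          ch[pos] <- mutate_bases(ch[pos])
          reads[i] <- paste(ch, collapse = "")
        }
      }
    }
    reads
  })
}

accept_prob <- function(frags, amplitude) {
  gc <- as.vector(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(frags), "GC")) / nchar(frags)
  (1 + amplitude * sin(2 * pi * gc)) / (1 + amplitude)
}

#' Write reads as FASTQ (constant quality)
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param prefix Read-name prefix.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads))
    writeLines(rbind(sprintf("@%s%d", prefix, seq_along(reads)), reads, "+",
                     vapply(nchar(reads), function(n)
                       strrep("I", n), "")), con)
  invisible(path)
}

## --------------------------------------------------------- stated scenarios

#' The diploid CNV benchmark scenario
#'
#' A 500 kb diploid with (coordinates in the final 505 kb reference):
#' a 5 kb segment at 100--105 kb duplicated into the reference at 400 kb
#' with 2% divergence (the diverged paralog pair), a hemizygous deletion at
#' 200--205 kb (truth 1), a homozygous tandem duplication at 300--305 kb
#' (truth 4), and a hemizygous deletion of the inserted paralog copy
#' (truth 1 at 400--405 kb; its partner stays at 2). Control regions are the
#' complement of the event intervals padded by 10 kb. Reads: 20x total,
#' 100 bp, 1% error, no GC bias.
#'
#' @param seed Master seed; sub-seeds are derived from it.
#' @param depth,read_length,error_rate,gc_bias Read simulation parameters.
#' @return List: `reference`, `control`, `truth`, `events`, `regions`
#'   (named truth intervals), `reads`.
#' @export
simulate_cnv_benchmark <- function(seed = 7L, depth = 20, read_length = 100L,
                                   error_rate = 0.01, gc_bias = 0) {
  base <- make_reference(500000L, gc = 0.41, seed = seed, name = "chr1")
  imp <- implant_duplication(base, "chr1", 100000L, 105000L,
                             insert_at = 400000L, divergence = 0.02,
                             seed = seed + 1L)
  ref <- imp$reference
  ev_h1 <- data.frame(
    chrom = "chr1",
    start = c(200000L, 300000L, 400000L), end = c(205000L, 305000L, 405000L),
    type = c("deletion", "duplication", "deletion"), stringsAsFactors = FALSE)
  ev_h2 <- data.frame(chrom = "chr1", start = 300000L, end = 305000L,
                      type = "duplication", stringsAsFactors = FALSE)
  truth <- truth_track(c(chr1 = nchar(ref[["chr1"]])), ev_h1, ev_h2)
  exclude <- data.frame(
    chrom = "chr1",
    start = c(90000L, 190000L, 290000L, 390000L),
    end = c(115000L, 215000L, 315000L, 415000L), stringsAsFactors = FALSE)
  control <- prepare_control(c(chr1 = nchar(ref[["chr1"]])), exclude)
  haps <- c(h1 = apply_events(ref, ev_h1)[["chr1"]],
            h2 = apply_events(ref, ev_h2)[["chr1"]])
  reads <- simulate_reads(haps, depth = depth, read_length = read_length,
                          error_rate = error_rate, gc_bias = gc_bias,
                          seed = seed + 2L)
  list(reference = ref, control = control, truth = truth,
       events = list(h1 = ev_h1, h2 = ev_h2),
       regions = list(
         hemizygous_deletion = c(200000L, 205000L),
         homozygous_duplication = c(300000L, 305000L),
         paralog_deleted = c(400000L, 405000L),
         paralog_partner = c(100000L, 105000L)),
       reads = reads)
}

#' Write a complete ready-to-run demo fixture directory
#'
#' A 100 kb toy genome with one diverged duplication and one hemizygous
#' deletion, plus control BED, truth BED, gene models and a 20x FASTQ —
#' everything needed to exercise the search/count/est/gene pipeline.
#'
#' @param dir Output directory (created).
#' @param seed Master seed.
#' @return Named list of the written paths, invisibly.
#' @export
simulate_paralog_demo <- function(dir, seed = 7L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- make_reference(100000L, gc = 0.41, seed = seed, name = "chr1")
  imp <- implant_duplication(base, "chr1", 20000L, 23000L, insert_at = 80000L,
                             divergence = 0.02, seed = seed + 1L)
  ref <- imp$reference
  ev_h1 <- data.frame(chrom = "chr1", start = 50000L, end = 53000L,
                      type = "deletion", stringsAsFactors = FALSE)
  truth <- truth_track(c(chr1 = nchar(ref[["chr1"]])), ev_h1, NULL)
  exclude <- data.frame(chrom = "chr1",
                        start = c(15000L, 45000L, 75000L),
                        end = c(28000L, 58000L, 88000L))
  control <- prepare_control(c(chr1 = nchar(ref[["chr1"]])), exclude)
  haps <- c(h1 = apply_events(ref, ev_h1)[["chr1"]], h2 = ref[["chr1"]])
  reads <- simulate_reads(haps, depth = 20, seed = seed + 2L)
  genes <- data.frame(
    chrom = "chr1",
    start = c(20500L, 80500L, 50500L, 10000L),
    end = c(22500L, 82500L, 52500L, 14000L),
    gene = c("PARA1", "PARA2", "DELG", "CTRLG"),
    transcript = c("t1", "t2", "t3", "t4"), stringsAsFactors = FALSE)
  paths <- list(reference = file.path(dir, "ref.fa"),
                control = file.path(dir, "control.bed"),
                truth = file.path(dir, "truth.bed"),
                genes = file.path(dir, "genes.tsv"),
                reads = file.path(dir, "reads.fastq"))
  write_fasta(ref, paths$reference)
  write_bed(control, paths$control)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(genes, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fastq(reads, paths$reads)
  invisible(paths)
}
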