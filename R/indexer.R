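# Catalog construction: enumerate genome k-mers, keep unique-exact ones,
# apply the substitution near-match filter, annotate with GC context and
# control flags, and serialize the index in chromosomal order.

## ---------------------------------------------------------------- input

# Normalize a reference to a named character vector of uppercase sequences.
# Accepts a FASTA path (optionally gzipped), a Biostrings::DNAStringSet, or
# an already-named character vector. Soft-masked lowercase is uppercased:
# masking is annotation, not sequence.
load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference) && length(reference) == 1L &&
             is.null(names(reference)) && file.exists(reference)) {
    seqs <- as.character(Biostrings::readDNAStringSet(reference))
  } else if (is.character(reference)) {
    seqs <- reference
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    stop("reference must be a FASTA path, DNAStringSet, or named character vector")
  }
  # FASTA descriptions: keep the first word as the sequence name
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  toupper(seqs)
}

## ----------------------------------------------------------- enumeration

#' Enumerate canonical k-mer occurrences of a reference
#'
#' Counts every length-`k` window of every sequence under canonical
#' encoding: a k-mer and its reverse complement accumulate in one entry.
#' Windows containing ambiguous characters contribute nothing.
#'
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param k K-mer length (<= 32).
#' @return A `kmer_occurrences` object: distinct canonical values (in order
#'   of first genome appearance), their occurrence counts, and the sequences
#'   for downstream location/GC annotation.
#' @export
enumerate_occurrences <- function(reference, k = 30L) {
  stopifnot(k >= 1, k <= 32)
  seqs <- load_reference(reference)
  enum <- cpp_enumerate(unname(seqs), as.integer(k))
  structure(
    list(values = enum$values, counts = enum$counts, ptr = enum$ptr,
         k = as.integer(k), seqs = seqs,
         seqnames = names(seqs), seqlengths = as.numeric(unname(nchar(seqs)))),
    class = "kmer_occurrences")
}

#' @export
print.kmer_occurrences <- function(x, ...) {
  cat(sprintf("<kmer_occurrences k=%d: %d distinct canonical k-mers over %d sequence(s)>\n",
              x$k, length(x$counts), length(x$seqnames)))
  invisible(x)
}

#' @exportS3Method as.data.frame kmer_occurrences
as.data.frame.kmer_occurrences <- function(x, ...) {
  data.frame(kmer = cpp_decode_many(x$values, x$k),
             count = x$counts, stringsAsFactors = FALSE)
}

new_kmer_set <- function(values, k) {
  structure(list(values = values, k = as.integer(k)), class = "kmer_set")
}

#' @export
length.kmer_set <- function(x) length(x$values) %/% 8L

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set k=%d: %d canonical k-mers>\n", x$k, length(x)))
  invisible(x)
}

#' @export
as.character.kmer_set <- function(x, ...) cpp_decode_many(x$values, x$k)

# Coerce a character vector / encoded_kmer / kmer_set to raw value buffer.
as_value_buffer <- function(x, k) {
  if (inherits(x, "kmer_set")) {
    stopifnot(x$k == k)
    x$values
  } else if (inherits(x, "encoded_kmer")) {
    stopifnot(x$k == k)
    x$value
  } else if (is.character(x)) {
    stopifnot(all(nchar(x) == k))
    vals <- lapply(x, function(s) encode_kmer(s)$value)
    cpp_canonical_many(do.call(c, c(vals, list(raw(0)))), k)
  } else if (is.raw(x)) {
    x
  } else {
    stop("cannot interpret k-mers from class ", paste(class(x), collapse = "/"))
  }
}

#' Candidate k-mers: those with a single exact occurrence
#'
#' @param occurrences A [enumerate_occurrences()] result.
#' @return A `kmer_set` of canonical k-mers with exact-occurrence count 1.
#' @export
select_candidates <- function(occurrences) {
  stopifnot(inherits(occurrences, "kmer_occurrences"))
  keep <- occurrences$counts == 1
  idx <- which(keep)
  sel <- as.vector(outer(1:8, (idx - 1L) * 8L, `+`))
  new_kmer_set(occurrences$values[sel], occurrences$k)
}

#' Near-match count of candidate k-mers
#'
#' Total genome occurrences of all distinct canonical k-mer variants at
#' substitution (Hamming) distance 1..`j` from each candidate; the candidate
#' itself is excluded, and variants that canonicalize to the same k-mer are
#' counted once. `j = 0` gives 0. A neighbor occurring five times in the
#' genome contributes five.
#'
#' @param candidates A `kmer_set`, `encoded_kmer`, or character vector.
#' @param occurrences The genome occurrence table the neighbors are looked
#'   up in.
#' @param j Edit distance, 0, 1 or 2 (substitutions only).
#' @param threads Worker threads; results are identical for any count.
#' @return Numeric vector of near-match counts, one per candidate.
#' @export
near_match_count <- function(candidates, occurrences, j = 2L, threads = 1L) {
  stopifnot(inherits(occurrences, "kmer_occurrences"), j %in% 0:2)
  vals <- as_value_buffer(candidates, occurrences$k)
  cpp_near_counts(vals, occurrences$ptr, occurrences$counts,
                  occurrences$k, as.integer(j), as.integer(threads))
}

#' Apply the near-match filter to candidate k-mers
#'
#' Retains a candidate iff its near-match count is strictly less than
#' `max_near` ("fewer than" is a strict inequality).
#'
#' @inheritParams near_match_count
#' @param max_near Threshold (default 100, strict less-than).
#' @return The retained `kmer_set`, with the near counts as attribute
#'   `near_counts`.
#' @export
filter_catalog <- function(candidates, occurrences, max_near = 100L, j = 2L,
                           threads = 1L) {
  stopifnot(inherits(candidates, "kmer_set"), max_near >= 1)
  near <- near_match_count(candidates, occurrences, j = j, threads = threads)
  idx <- which(near < max_near)
  sel <- as.vector(outer(1:8, (idx - 1L) * 8L, `+`))
  out <- new_kmer_set(candidates$values[sel], candidates$k)
  attr(out, "near_counts") <- near[idx]
  out
}

## -------------------------------------------------------- control regions

# Normalize control regions to a merged, non-overlapping 0-based half-open
# data.frame(chrom, start, end). Accepts a 3-column BED path or data.frame.
control_regions <- function(x) {
  if (is.null(x)) return(data.frame(chrom = character(), start = integer(),
                                    end = integer()))
  bed <- if (is.character(x) && length(x) == 1L) read_bed3(x) else
    as.data.frame(x)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  stopifnot(all(bed$end > bed$start))
  merged <- do.call(rbind, lapply(split(bed, bed$chrom), function(b) {
    r <- IRanges::reduce(IRanges::IRanges(start = b$start + 1L, end = b$end))
    data.frame(chrom = b$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  merged[order(merged$chrom, merged$start), , drop = FALSE]
}

read_bed3 <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
  bed
}

#' Write intervals as 3-column BED
#' @param bed data.frame(chrom, start, end), 0-based half-open.
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build an include-BED of putatively copy-number-invariant regions
#'
#' Merges exclusion tracks (segmental duplications, known CNVs,
#' non-autosomes, ...) and complements them against the chromosome lengths,
#' reproducing at any scale the usual construction of the control file.
#'
#' @param genome Named vector of sequence lengths, or a two-column
#'   chrom-sizes file path.
#' @param exclude A BED path / data.frame, or a list of them.
#' @return data.frame(chrom, start, end) of regions to include.
#' @export
prepare_control <- function(genome, exclude = list()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gs <- read.table(genome, sep = "\t", header = FALSE,
                     col.names = c("chrom", "size"),
                     colClasses = c("character", "integer"))
    genome <- setNames(gs$size, gs$chrom)
  }
  stopifnot(!is.null(names(genome)))
  if (!is.list(exclude) || is.data.frame(exclude)) exclude <- list(exclude)
  excl <- if (length(exclude))
    control_regions(do.call(rbind, lapply(exclude, function(x)
      setNames(if (is.character(x)) read_bed3(x) else as.data.frame(x)[, 1:3],
               c("chrom", "start", "end")))))
  else control_regions(NULL)
  out <- lapply(names(genome), function(chr) {
    len <- unname(genome[[chr]])
    e <- excl[excl$chrom == chr, , drop = FALSE]
    gaps <- IRanges::gaps(
      IRanges::reduce(IRanges::IRanges(start = e$start + 1L, end = e$end)),
      start = 1L, end = len)
    if (length(gaps) == 0) return(NULL)
    data.frame(chrom = chr, start = IRanges::start(gaps) - 1L,
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## ------------------------------------------------------------ annotation

#' Locate retained k-mers and annotate GC context and control flags
#'
#' Each retained k-mer occurs exactly once in the reference; its record
#' carries the forward-strand 0-based start, a control flag (true iff the
#' k-mer interval lies entirely within a control interval), and the GC
#' fraction of the `gc_window` bp window centered on the k-mer midpoint
#' (clipped at chromosome ends). Records are sorted chromosomally.
#'
#' @param retained `kmer_set` from [filter_catalog()].
#' @param occurrences The [enumerate_occurrences()] result for the same
#'   reference.
#' @param control Control regions (BED path or data.frame), or `NULL`.
#' @param gc_window GC context window in bp (default 400).
#' @param edit_distance,max_near Provenance parameters recorded in the
#'   catalog.
#' @return A `kmer_catalog`.
#' @export
locate_and_annotate <- function(retained, occurrences, control = NULL,
                                gc_window = 400L, edit_distance = 2L,
                                max_near = 100L) {
  stopifnot(inherits(retained, "kmer_set"),
            inherits(occurrences, "kmer_occurrences"))
  k <- occurrences$k
  loc <- cpp_locate(unname(occurrences$seqs), k, retained$values)
  ord <- order(loc$chrom, loc$start)
  chrom <- loc$chrom[ord] + 1L           # 1-based index into seqnames
  start <- loc$start[ord]
  sel <- as.vector(outer(1:8, (ord - 1L) * 8L, `+`))
  values <- retained$values[sel]

  gc <- numeric(length(start))
  for (ci in unique(chrom)) {
    ix <- which(chrom == ci)
    gc[ix] <- cpp_gc_fraction(occurrences$seqs[[ci]], start[ix], k,
                              as.integer(gc_window))
  }

  ctrl <- control_regions(control)
  is_control <- logical(length(start))
  for (ci in unique(chrom)) {
    cname <- occurrences$seqnames[ci]
    b <- ctrl[ctrl$chrom == cname, , drop = FALSE]
    if (nrow(b) == 0) next
    ix <- which(chrom == ci)
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(start = start[ix] + 1L, width = k),
      IRanges::IRanges(start = b$start + 1L, end = b$end),
      type = "within")
    is_control[ix] <- hits
  }

  structure(
    list(seqnames = occurrences$seqnames, seqlengths = occurrences$seqlengths,
         chrom = chrom, start = start, values = values,
         is_control = is_control, gc = gc,
         k = k, edit_distance = as.integer(edit_distance),
         max_near = as.integer(max_near), gc_window = as.integer(gc_window)),
    class = "kmer_catalog")
}

#' @export
length.kmer_catalog <- function(x) length(x$start)

#' @export
print.kmer_catalog <- function(x, ...) {
  cat(sprintf(paste0("<kmer_catalog k=%d j=%d max_near=%d: %d k-mers ",
                     "(%d control) over %d sequence(s)>\n"),
              x$k, x$edit_distance, x$max_near, length(x),
              sum(x$is_control), length(x$seqnames)))
  invisible(x)
}

#' @exportS3Method as.data.frame kmer_catalog
as.data.frame.kmer_catalog <- function(x, ...) {
  data.frame(chrom = x$seqnames[x$chrom], start = x$start,
             end = x$start + x$k, kmer = cpp_decode_many(x$values, x$k),
             is_control = x$is_control, gc = x$gc, stringsAsFactors = FALSE)
}

# Stable identity used to bind count files to the index they came from.
catalog_checksum <- function(catalog) {
  hdr <- writeBin(c(catalog$k, catalog$edit_distance, catalog$max_near,
                    length(catalog$start)), raw(), size = 4,
                  endian = "little")
  cpp_djb2_hex(c(hdr, catalog$values))
}

#' Build the analyzable-k-mer catalog from a reference genome
#'
#' The full search stage: enumerate all canonical k-mers, keep those with a
#' single exact occurrence, drop candidates with `max_near` or more genome
#' occurrences of substitution neighbors within edit distance
#' `edit_distance`, and annotate the survivors with position, GC context and
#' control flags.
#'
#' @inheritParams enumerate_occurrences
#' @inheritParams locate_and_annotate
#' @param edit_distance Substitution distance j for the near-match search
#'   (0, 1 or 2; default 2).
#' @param max_near Retain k-mers with strictly fewer near matches
#'   (default 100).
#' @param threads Worker threads for the near-match search (results are
#'   thread-count invariant).
#' @return A `kmer_catalog`.
#' @export
kmer_search <- function(reference, control = NULL, k = 30L,
                        edit_distance = 2L, max_near = 100L,
                        gc_window = 400L, threads = 1L) {
  occ <- enumerate_occurrences(reference, k = k)
  cand <- select_candidates(occ)
  kept <- filter_catalog(cand, occ, max_near = max_near, j = edit_distance,
                         threads = threads)
  locate_and_annotate(kept, occ, control = control, gc_window = gc_window,
                      edit_distance = edit_distance, max_near = max_near)
}

## ----------------------------------------------------------- serialization

INDEX_MAGIC <- "KMCNIDX1"

#' Write / read a k-mer catalog index file
#'
#' Binary layout (little-endian): 8-byte magic, int32 version, int32 k, j,
#' max_near, gc_window, the sequence dictionary (count, then per sequence a
#' length-prefixed name and a double length), the record count, then the
#' column arrays (chrom int32, start int32, packed values 8 bytes/k-mer,
#' control flags 1 byte, gc double). Round trips are bit-exact.
#'
#' @param catalog A `kmer_catalog`.
#' @param path File path.
#' @export
write_index <- function(catalog, path) {
  stopifnot(inherits(catalog, "kmer_catalog"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(c(1L, catalog$k, catalog$edit_distance, catalog$max_near,
             catalog$gc_window), con, size = 4, endian = "little")
  writeBin(length(catalog$seqnames), con, size = 4, endian = "little")
  for (i in seq_along(catalog$seqnames)) {
    nm <- charToRaw(catalog$seqnames[i])
    writeBin(length(nm), con, size = 4, endian = "little")
    writeBin(nm, con)
    writeBin(as.double(catalog$seqlengths[i]), con, endian = "little")
  }
  n <- length(catalog$start)
  writeBin(as.double(n), con, endian = "little")
  writeBin(catalog$chrom, con, size = 4, endian = "little")
  writeBin(catalog$start, con, size = 4, endian = "little")
  writeBin(catalog$values, con)
  writeBin(as.raw(catalog$is_control), con)
  writeBin(catalog$gc, con, endian = "little")
  invisible(path)
}

index_format_error <- function(msg) {
  stop(structure(class = c("kmercn_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @rdname write_index
#' @param k If given, error unless the stored index was built with this k
#'   (parameter mismatch guard).
#' @export
read_index <- function(path, k = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  need <- function(what, n, size = NA, endian = "little") {
    out <- if (identical(what, "raw")) readBin(con, raw(), n = n)
           else readBin(con, what, n = n, size = size, endian = endian)
    if (length(out) != n) index_format_error("truncated or corrupt index file")
    out
  }
  magic <- need("raw", nchar(INDEX_MAGIC))
  if (!identical(rawToChar(magic), INDEX_MAGIC))
    index_format_error("not a kmercn index file (bad magic)")
  hdr <- need(integer(), 5, size = 4)
  if (hdr[1] != 1L) index_format_error("unsupported index version")
  if (!is.null(k) && hdr[2] != k)
    index_format_error(sprintf("parameter mismatch: index built with k=%d, requested k=%d",
                               hdr[2], k))
  n_seq <- need(integer(), 1, size = 4)
  seqnames <- character(n_seq)
  seqlengths <- numeric(n_seq)
  for (i in seq_len(n_seq)) {
    nl <- need(integer(), 1, size = 4)
    seqnames[i] <- rawToChar(need("raw", nl))
    seqlengths[i] <- need(numeric(), 1)
  }
  n <- as.integer(need(numeric(), 1))
  structure(
    list(seqnames = seqnames, seqlengths = seqlengths,
         chrom = need(integer(), n, size = 4),
         start = need(integer(), n, size = 4),
         values = need("raw", 8L * n),
         is_control = as.logical(need("raw", n)),
         gc = need(numeric(), n),
         k = hdr[2], edit_distance = hdr[3], max_near = hdr[4],
         gc_window = hdr[5]),
    class = "kmer_catalog")
}

#' Dump a catalog as TSV for inspection
#' @param catalog A `kmer_catalog`.
#' @param path Output path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
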