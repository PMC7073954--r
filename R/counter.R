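# Read-stream consumption: parse FASTQ/FASTA/raw sequence streams and
# tabulate catalog k-mer occurrences. Upstream read QC (duplicates,
# secondary alignments, failed-QC) is the caller's job, e.g.
#   samtools fasta -F 3840 in.cram | kmercn count ...

#' Parse a sequence stream into uppercase read sequences
#'
#' Auto-detects the format from the first non-empty character: `@` FASTQ,
#' `>` FASTA, anything else one raw sequence per line. Quality lines and
#' headers are discarded; multi-line FASTA records are concatenated.
#'
#' @param input A file path, a connection (e.g. `file("stdin")`), or a
#'   character vector of stream lines.
#' @return Character vector of uppercase sequences.
#' @export
parse_sequences <- function(input) {
  lines <- if (inherits(input, "connection")) {
    readLines(input, warn = FALSE)
  } else if (is.character(input) && length(input) == 1L &&
             !grepl("[\n@>]", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (is.character(input)) {
    if (length(input) == 1L && grepl("\n", input))
      strsplit(input, "\n", fixed = TRUE)[[1]]
    else input
  } else {
    stop("input must be a path, connection, or character vector of lines")
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(character(0))
  first <- substr(lines[1], 1, 1)
  seqs <- if (first == "@") parse_fastq(lines)
          else if (first == ">") parse_fasta_lines(lines)
          else lines
  toupper(seqs)
}

parse_fastq <- function(lines) {
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: line count not a multiple of 4")
  ids <- seq(1, length(lines), by = 4)
  seqs <- lines[ids + 1]
  plus <- lines[ids + 2]
  quals <- lines[ids + 3]
  if (any(substr(plus, 1, 1) != "+"))
    stop(sprintf("malformed FASTQ record %d: separator line does not start with '+'",
                 which(substr(plus, 1, 1) != "+")[1]))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d: sequence and quality lengths differ",
                 bad[1]))
  seqs
}

parse_fasta_lines <- function(lines) {
  is_hdr <- startsWith(lines, ">")
  rec <- cumsum(is_hdr)
  body <- !is_hdr
  unname(vapply(split(lines[body], rec[body]), paste, "", collapse = ""))
}

## ------------------------------------------------------------ count table

new_count_table <- function(counts, total_reads, total_kmers_scanned,
                            checksum, k) {
  structure(list(counts = counts, total_reads = total_reads,
                 total_kmers_scanned = total_kmers_scanned,
                 checksum = checksum, k = k),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table: %d catalog k-mers, %g reads, %g windows scanned, sum %g>\n",
              length(x$counts), x$total_reads, x$total_kmers_scanned,
              sum(x$counts)))
  invisible(x)
}

#' Count catalog k-mer occurrences in a read stream
#'
#' Every length-k window of every read (step 1 along the read) is
#' canonicalized and, if present in the catalog, its count incremented.
#' Windows with ambiguous bases are skipped; non-catalog windows are
#' ignored; reads shorter than k contribute nothing.
#'
#' @param catalog A `kmer_catalog` (or path to an index file).
#' @param input Read stream: path, connection, or character vector (see
#'   [parse_sequences()]); alternatively a character vector of bare
#'   sequences via `raw_sequences = TRUE`.
#' @param workers Number of counting workers; reads are partitioned
#'   round-robin and per-worker tables merged, so results are invariant to
#'   the worker count.
#' @param raw_sequences If `TRUE`, `input` is already a vector of sequences.
#' @return A `count_table` aligned to catalog (chromosomal) order.
#' @export
count_kmers <- function(catalog, input, workers = 1L, raw_sequences = FALSE) {
  if (is.character(catalog) && length(catalog) == 1L) catalog <- read_index(catalog)
  stopifnot(inherits(catalog, "kmer_catalog"), workers >= 1)
  seqs <- if (raw_sequences) toupper(input) else parse_sequences(input)
  chk <- catalog_checksum(catalog)
  if (workers == 1L || length(seqs) < 2L) {
    ctr <- cpp_counter_new(catalog$values, catalog$k)
    cpp_counter_feed(ctr, seqs)
    res <- cpp_counter_collect(ctr)
    return(new_count_table(res$counts, res$total_reads,
                           res$total_kmers_scanned, chk, catalog$k))
  }
  parts <- split(seqs, rep_len(seq_len(workers), length(seqs)))
  tables <- lapply(parts, function(p)
    count_kmers(catalog, p, workers = 1L, raw_sequences = TRUE))
  merge_counts(tables)
}

#' Add one sequence's k-mer windows to a count table
#'
#' Functional single-sequence update used to express the streaming
#' contract; [count_kmers()] is the efficient bulk path.
#'
#' @param seq A DNA string.
#' @param catalog A `kmer_catalog`.
#' @param table An existing `count_table` for this catalog, or `NULL` to
#'   start from zero.
#' @return The updated `count_table`.
#' @export
count_sequence <- function(seq, catalog, table = NULL) {
  one <- count_kmers(catalog, seq, raw_sequences = TRUE)
  if (is.null(table)) return(one)
  merge_counts(list(table, one))
}

#' Merge per-worker count tables
#'
#' Element-wise sum; associative and commutative, so partitioning reads
#' across workers cannot change results. All tables must come from the same
#' catalog (checksum-checked).
#'
#' @param tables List of `count_table`s.
#' @return The merged `count_table`.
#' @export
merge_counts <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "count_table")))
  chk <- vapply(tables, function(t) t$checksum, "")
  if (length(unique(chk)) != 1L)
    stop("cannot merge: count tables were built against different catalogs")
  new_count_table(
    counts = Reduce(`+`, lapply(tables, `[[`, "counts")),
    total_reads = sum(vapply(tables, `[[`, 0, "total_reads")),
    total_kmers_scanned = sum(vapply(tables, `[[`, 0, "total_kmers_scanned")),
    checksum = chk[1], k = tables[[1]]$k)
}

## ----------------------------------------------------------- serialization

COUNTS_MAGIC <- "KMCNCNT1"

#' Write / read a count table
#'
#' Binary little-endian layout with the catalog checksum embedded so
#' downstream estimation can refuse counts from a different index.
#'
#' @param table A `count_table`.
#' @param path File path.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(COUNTS_MAGIC), con)
  writeBin(c(1L, table$k), con, size = 4, endian = "little")
  chk <- charToRaw(table$checksum)
  writeBin(length(chk), con, size = 4, endian = "little")
  writeBin(chk, con)
  writeBin(as.double(c(length(table$counts), table$total_reads,
                       table$total_kmers_scanned)), con, endian = "little")
  writeBin(as.double(table$counts), con, endian = "little")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  need <- function(what, n, size = NA) {
    out <- if (identical(what, "raw")) readBin(con, raw(), n = n)
           else readBin(con, what, n = n, size = size, endian = "little")
    if (length(out) != n) index_format_error("truncated or corrupt counts file")
    out
  }
  magic <- need("raw", nchar(COUNTS_MAGIC))
  if (!identical(rawToChar(magic), COUNTS_MAGIC))
    index_format_error("not a kmercn counts file (bad magic)")
  hdr <- need(integer(), 2, size = 4)
  if (hdr[1] != 1L) index_format_error("unsupported counts version")
  nchk <- need(integer(), 1, size = 4)
  checksum <- rawToChar(need("raw", nchk))
  meta <- need(numeric(), 3)
  counts <- need(numeric(), as.integer(meta[1]))
  new_count_table(counts, meta[2], meta[3], checksum, hdr[2])
}
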