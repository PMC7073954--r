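# 2-bit k-mer codec and the open-addressing k-mer table.
#
# A k-mer of length k <= 32 is packed two bits per base into a 64-bit value,
# 3' base in the least-significant bits. The per-base code is bits 1-2 of the
# base's ASCII character (A=0, C=1, T=2, G=3), which makes complementation
# (code - 2) mod 4. R doubles lose integer exactness past 2^53, so the value
# is carried as 8 raw bytes, most-significant byte first.

new_encoded_kmer <- function(value, k) {
  structure(list(value = value, k = as.integer(k)), class = "encoded_kmer")
}

#' Encode a DNA k-mer into its 2-bit packed value
#'
#' @param seq A single DNA string, 1--32 bases, case-insensitive. Any
#'   ambiguity code (`N`, `R`, ...) rejects the k-mer with a classed error
#'   (`kmercn_kmer_reject`), distinguishable from other failures.
#' @return An `encoded_kmer`: the packed 64-bit value (8 raw bytes,
#'   most-significant first) plus the k-mer length.
#' @examples
#' kmer_value(encode_kmer("ACGT"))  # 30
#' @export
encode_kmer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  v <- cpp_encode(seq)
  if (is.null(v)) {
    stop(structure(
      class = c("kmercn_kmer_reject", "error", "condition"),
      list(message = sprintf("k-mer rejected: ambiguous base in '%s'", seq),
           call = sys.call(-1))
    ))
  }
  new_encoded_kmer(v, nchar(seq))
}

#' Decode a packed k-mer back to its DNA string
#' @param x An `encoded_kmer`.
#' @return Uppercase DNA string of length `x$k`.
#' @export
decode_kmer <- function(x) {
  stopifnot(inherits(x, "encoded_kmer"))
  cpp_decode(x$value, x$k)
}

raw8_to_num <- function(r) {
  # exact only below 2^53: top 11 bits must be clear
  if (as.integer(r[1]) != 0L || as.integer(r[2]) >= 0x20L)
    stop("value exceeds 2^53 and cannot be held exactly in an R double; ",
         "use the raw bytes or kmer_hex()")
  Reduce(function(acc, b) acc * 256 + as.integer(b), as.list(r), 0)
}

#' Numeric value of an encoded k-mer
#'
#' Errors if the value is at or above 2^53 (no exact double representation);
#' use [kmer_hex()] for arbitrary k.
#' @param x An `encoded_kmer`.
#' @export
kmer_value <- function(x) {
  stopifnot(inherits(x, "encoded_kmer"))
  raw8_to_num(x$value)
}

#' Hexadecimal value of an encoded k-mer
#' @param x An `encoded_kmer`.
#' @export
kmer_hex <- function(x) {
  stopifnot(inherits(x, "encoded_kmer"))
  paste(format(x$value), collapse = "")
}

#' Reverse complement in encoded space
#'
#' Complements each 2-bit slot by (code - 2) mod 4 and reverses slot order;
#' `revcomp_encoded(revcomp_encoded(x))` is `x`.
#' @param x An `encoded_kmer`.
#' @export
revcomp_encoded <- function(x) {
  stopifnot(inherits(x, "encoded_kmer"))
  new_encoded_kmer(cpp_revcomp(x$value, x$k), x$k)
}

#' Canonical form of an encoded k-mer
#'
#' A k-mer and its reverse complement are equivalent; the canonical form is
#' the numerically smaller of the two encodings.
#' @param x An `encoded_kmer`.
#' @export
canonical_kmer <- function(x) {
  stopifnot(inherits(x, "encoded_kmer"))
  new_encoded_kmer(cpp_canonical(x$value, x$k), x$k)
}

#' @export
print.encoded_kmer <- function(x, ...) {
  cat(sprintf("<encoded_kmer k=%d %s value=0x%s>\n",
              x$k, decode_kmer(x), kmer_hex(x)))
  invisible(x)
}

#' @export
`==.encoded_kmer` <- function(e1, e2) {
  identical(e1$value, e2$value) && identical(e1$k, e2$k)
}

#' DJB2 hash of a byte sequence
#'
#' Classic multiplicative DJB2: h starts at 5381 and is updated as
#' h * 33 + byte with 64-bit wraparound. Returns a numeric when the result
#' is exactly representable (below 2^53), else errors; `hex = TRUE` always
#' works.
#' @param bytes A raw vector, or a single character string (hashed as its
#'   ASCII bytes).
#' @param hex Return the 64-bit hash as a 16-character hex string.
#' @examples
#' djb2(raw(0))         # 5381, the seed
#' djb2(as.raw(0x41))   # 5381*33 + 65 = 177638
#' @export
djb2 <- function(bytes, hex = FALSE) {
  if (is.character(bytes)) bytes <- charToRaw(bytes)
  stopifnot(is.raw(bytes))
  if (hex) cpp_djb2_hex(bytes) else raw8_to_num(cpp_djb2(bytes))
}

#' Hash index of an encoded k-mer
#'
#' DJB2 of the 8 bytes of the value (most-significant byte first) modulo the
#' table capacity. Deterministic; used as the probe start of the k-mer table.
#' @param x An `encoded_kmer`.
#' @param capacity Number of table cells (>= 1).
#' @return 0-based cell index in `[0, capacity)`.
#' @export
hash_index <- function(x, capacity) {
  stopifnot(inherits(x, "encoded_kmer"))
  cpp_hash_index(x$value, capacity)
}

#' Open-addressing k-mer hash table
#'
#' Linear probing with a half-flipped direction: a probe sequence whose hash
#' index falls in the lower half of the array advances toward increasing
#' indices, one starting in the upper half toward decreasing indices, and
#' never wraps around. Cell indices are 0-based, matching [hash_index()].
#' @param capacity Number of cells.
#' @export
kmer_table <- function(capacity) {
  stopifnot(capacity >= 1)
  structure(list(ptr = cpp_table_new(capacity), capacity = capacity),
            class = "kmer_hash_table")
}

#' Insert an encoded k-mer into a table
#'
#' Stores the key at its hash index if that cell is empty, otherwise at the
#' first empty cell along the half-dependent probe direction. Re-inserting a
#' present key returns its existing cell and leaves occupancy unchanged.
#' @param table A [kmer_table()].
#' @param x An `encoded_kmer`.
#' @return The 0-based cell index used.
#' @export
table_insert <- function(table, x) {
  stopifnot(inherits(table, "kmer_hash_table"), inherits(x, "encoded_kmer"))
  cpp_table_insert(table$ptr, x$value)
}

#' Look up an encoded k-mer in a table
#' @param table A [kmer_table()].
#' @param x An `encoded_kmer`.
#' @return The 0-based cell index, or `NA` if absent. The scan never moves
#'   past an empty cell.
#' @export
table_lookup <- function(table, x) {
  stopifnot(inherits(table, "kmer_hash_table"), inherits(x, "encoded_kmer"))
  cell <- cpp_table_lookup(table$ptr, x$value)
  if (cell < 0) NA_real_ else cell
}

#' Number of occupied cells in a table
#' @param table A [kmer_table()].
#' @export
table_occupancy <- function(table) {
  stopifnot(inherits(table, "kmer_hash_table"))
  cpp_table_occupancy(table$ptr)
}
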