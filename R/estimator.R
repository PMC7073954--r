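# GC-bias correction and conversion of raw k-mer counts into windowed
# diploid copy-number tracks.
#
# Model: control k-mers (those inside copy-number-invariant regions) are
# binned by local GC fraction; each bin's multiplicative correction factor
# is (global control mean count) / (bin mean count). Corrected counts are
# then scaled so that the mean corrected control count maps to copy
# number 2, the diploid baseline.

#' Fit the GC correction curve on control k-mers
#'
#' @param counts A `count_table`.
#' @param catalog The `kmer_catalog` the counts were tabulated against.
#' @param bin_width GC-fraction bin width (default 0.01).
#' @param min_control_per_bin Bins with fewer control k-mers than this
#'   inherit the nearest qualified bin's factor (default 100).
#' @return A `gc_curve`: per-bin tallies, mean control counts and factors,
#'   with the global control mean as attribute `global_mean`.
#' @export
fit_gc_curve <- function(counts, catalog, bin_width = 0.01,
                         min_control_per_bin = 100L) {
  stopifnot(inherits(counts, "count_table"), inherits(catalog, "kmer_catalog"))
  check_binding(counts, catalog)
  ctrl <- which(catalog$is_control)
  if (length(ctrl) == 0)
    stop("no control k-mers in catalog: a control-region BED is required ",
         "for GC correction and the diploid baseline")
  x <- counts$counts[ctrl]
  if (all(x == 0))
    stop("all control k-mer counts are zero: sample stream was empty ",
         "or unrelated to this reference")
  nbin <- as.integer(ceiling(1 / bin_width))
  bin <- pmin(floor(catalog$gc[ctrl] / bin_width) + 1L, nbin)
  tally <- tabulate(bin, nbins = nbin)
  sums <- vapply(seq_len(nbin), function(b) sum(x[bin == b]), 0)
  bin_mean <- ifelse(tally > 0, sums / pmax(tally, 1L), NA_real_)
  global_mean <- mean(x)
  qualified <- tally >= min_control_per_bin & !is.na(bin_mean) & bin_mean > 0
  if (!any(qualified)) {
    qualified <- tally > 0 & !is.na(bin_mean) & bin_mean > 0
    warning("no GC bin reached min_control_per_bin = ", min_control_per_bin,
            "; using every non-empty bin with a positive mean")
  }
  factor <- rep(NA_real_, nbin)
  factor[qualified] <- global_mean / bin_mean[qualified]
  qidx <- which(qualified)
  for (b in which(!qualified)) {
    nearest <- qidx[which.min(abs(qidx - b))]
    factor[b] <- factor[nearest]
  }
  structure(
    data.frame(bin = seq_len(nbin), gc_lo = (seq_len(nbin) - 1) * bin_width,
               gc_hi = pmin(seq_len(nbin) * bin_width, 1),
               n_control = tally, mean_count = bin_mean,
               factor = factor, qualified = qualified),
    class = c("gc_curve", "data.frame"),
    global_mean = global_mean, bin_width = bin_width)
}

gc_bin_of <- function(gc, bin_width, nbin) {
  pmin(floor(gc / bin_width) + 1L, nbin)
}

#' Apply a GC correction curve to raw counts
#'
#' Every catalog k-mer, control and non-control alike, is multiplied by the
#' factor of its GC bin.
#'
#' @inheritParams fit_gc_curve
#' @param curve A [fit_gc_curve()] result.
#' @return Numeric vector of corrected counts in catalog order.
#' @export
apply_correction <- function(counts, catalog, curve) {
  stopifnot(inherits(curve, "gc_curve"))
  check_binding(counts, catalog)
  bw <- attr(curve, "bin_width")
  bin <- gc_bin_of(catalog$gc, bw, nrow(curve))
  counts$counts * curve$factor[bin]
}

#' Convert corrected counts to per-k-mer diploid copy number
#'
#' `cn = 2 * corrected / mu` where `mu` is the mean corrected count over
#' control k-mers — the depth corresponding to the diploid state.
#'
#' @param corrected Corrected counts from [apply_correction()].
#' @param catalog The matching `kmer_catalog`.
#' @return Numeric vector of copy numbers in catalog order.
#' @export
counts_to_cn <- function(corrected, catalog) {
  stopifnot(inherits(catalog, "kmer_catalog"),
            length(corrected) == length(catalog))
  mu <- mean(corrected[catalog$is_control])
  if (!is.finite(mu) || mu == 0)
    stop("diploid baseline is zero: no sequencing signal at control k-mers")
  2 * corrected / mu
}

#' Summarize per-k-mer copy number into fixed-k-mer-count windows
#'
#' Consecutive catalog k-mers on one chromosome are grouped `window_kmers`
#' at a time; a window spans from the 5' end of its first k-mer to the 3'
#' end (exclusive) of its last. Terminal groups with fewer than
#' `window_kmers` k-mers are dropped unless `keep_partial`. Windows never
#' span chromosomes.
#'
#' @param cn Per-k-mer copy numbers aligned to the catalog.
#' @param catalog The matching `kmer_catalog`.
#' @param window_kmers K-mers per window (default 1000).
#' @param stat Window statistic, `"mean"` (default) or `"median"`.
#' @param keep_partial Keep terminal sub-size windows, flagged by their true
#'   `n_kmers`.
#' @return A `cn_track` data.frame (chrom, start, end, cn, n_kmers).
#' @export
window_track <- function(cn, catalog, window_kmers = 1000L,
                         stat = c("mean", "median"), keep_partial = FALSE) {
  stopifnot(inherits(catalog, "kmer_catalog"), length(cn) == length(catalog),
            window_kmers >= 1)
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else median
  W <- as.integer(window_kmers)
  rows <- lapply(unique(catalog$chrom), function(ci) {
    ix <- which(catalog$chrom == ci)    # catalog already in chromosomal order
    nw <- length(ix) %/% W
    n_full <- nw * W
    grp <- rep(seq_len(nw), each = W)
    if (keep_partial && length(ix) > n_full) {
      grp <- c(grp, rep(nw + 1L, length(ix) - n_full))
      nw <- nw + 1L
    }
    if (nw == 0) return(NULL)
    used <- ix[seq_along(grp)]
    first <- used[!duplicated(grp)]
    last <- used[!duplicated(grp, fromLast = TRUE)]
    data.frame(
      chrom = catalog$seqnames[ci],
      start = catalog$start[first],
      end = catalog$start[last] + catalog$k,
      cn = vapply(split(cn[used], grp), fun, 0),
      n_kmers = tabulate(grp, nbins = nw),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), cn = numeric(), n_kmers = integer())
  rownames(out) <- NULL
  structure(out, class = c("cn_track", "data.frame"),
            window_kmers = W, stat = stat)
}

check_binding <- function(counts, catalog) {
  stopifnot(inherits(counts, "count_table"), inherits(catalog, "kmer_catalog"))
  if (!identical(counts$checksum, catalog_checksum(catalog)))
    stop("count table was built against a different index ",
         "(catalog checksum mismatch)")
  if (length(counts$counts) != length(catalog))
    stop("count table length does not match catalog")
  invisible(TRUE)
}

#' Estimate a windowed copy-number track from raw counts
#'
#' Full estimation stage: fit the GC curve on control k-mers, correct all
#' counts, convert to diploid copy number, and window the result.
#'
#' @inheritParams fit_gc_curve
#' @inheritParams window_track
#' @param per_kmer Also return per-k-mer corrected counts and copy numbers.
#' @return A `cn_track`; with `per_kmer = TRUE`, a list
#'   `(track, cn, corrected, curve)`.
#' @export
estimate_cn <- function(catalog, counts, window_kmers = 1000L,
                        stat = c("mean", "median"), keep_partial = FALSE,
                        bin_width = 0.01, min_control_per_bin = 100L,
                        per_kmer = FALSE) {
  if (is.character(catalog) && length(catalog) == 1L) catalog <- read_index(catalog)
  if (is.character(counts) && length(counts) == 1L) counts <- read_counts(counts)
  curve <- fit_gc_curve(counts, catalog, bin_width = bin_width,
                        min_control_per_bin = min_control_per_bin)
  corrected <- apply_correction(counts, catalog, curve)
  cn <- counts_to_cn(corrected, catalog)
  track <- window_track(cn, catalog, window_kmers = window_kmers,
                        stat = stat, keep_partial = keep_partial)
  if (per_kmer) list(track = track, cn = cn, corrected = corrected,
                     curve = curve)
  else track
}

## ------------------------------------------------------------- BED output

#' Write / read a copy-number track as 4-column BED
#'
#' 0-based half-open intervals, copy number printed with 4 decimal places,
#' preceded by a `#` header comment.
#'
#' @param track A `cn_track`.
#' @param path Output path.
#' @export
write_track_bed <- function(track, path) {
  stopifnot(inherits(track, "cn_track") || is.data.frame(track))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tcn", con)
  if (nrow(track) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%.4f", track$chrom,
                       as.integer(track$start), as.integer(track$end),
                       track$cn), con)
  invisible(path)
}

#' @rdname write_track_bed
#' @export
read_track_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), cn = numeric(),
                      n_kmers = integer())
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    out <- data.frame(chrom = vapply(f, `[`, "", 1),
                      start = as.integer(vapply(f, `[`, "", 2)),
                      end = as.integer(vapply(f, `[`, "", 3)),
                      cn = as.numeric(vapply(f, `[`, "", 4)),
                      n_kmers = NA_integer_, stringsAsFactors = FALSE)
  }
  structure(out, class = c("cn_track", "data.frame"))
}
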