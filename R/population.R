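# Multi-sample summarization: per-sample QC, cross-sample window ranges,
# gene-level copy numbers with male chrX handling, heatmap BEDs and UCSC
# track-hub emission.

track_cn <- function(x) {
  if (inherits(x, "cn_track") || is.data.frame(x)) x$cn else as.numeric(x)
}

#' Median absolute deviation of a copy-number track
#'
#' Unscaled MAD (no 1.4826 consistency factor): the median of absolute
#' deviations from the median window copy number. A per-sample noise metric.
#'
#' @param track A `cn_track` or numeric vector of window copy numbers.
#' @export
sample_mad <- function(track) {
  cn <- track_cn(track)
  if (length(cn) == 0) stop("empty track: MAD undefined")
  median(abs(cn - median(cn)))
}

#' Fraction of windows outside the diploid band
#'
#' Fraction of windows with raw copy number strictly below `lower` or
#' strictly above `upper`; the boundary values themselves are not outliers.
#'
#' @inheritParams sample_mad
#' @param lower,upper Band limits (defaults 1.5 and 2.5).
#' @export
outlier_fraction <- function(track, lower = 1.5, upper = 2.5) {
  cn <- track_cn(track)
  if (length(cn) == 0) stop("empty track: outlier fraction undefined")
  mean(cn < lower | cn > upper)
}

#' Per-sample QC summary
#'
#' @param tracks Named list of `cn_track`s (one per sample).
#' @return data.frame(sample, mad, frac_outside).
#' @export
sample_summary <- function(tracks) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  data.frame(sample = names(tracks),
             mad = vapply(tracks, sample_mad, 0),
             frac_outside = vapply(tracks, outlier_fraction, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-window copy-number range across samples
#'
#' All tracks must share identical window coordinates.
#'
#' @param tracks List of `cn_track`s.
#' @return data.frame(chrom, start, end, min, max, mean, range).
#' @export
window_ranges <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!identical(ref$chrom, t$chrom) || !identical(ref$start, t$start) ||
        !identical(ref$end, t$end))
      stop("window coordinates differ between samples; tracks must come ",
           "from the same index and window size")
  }
  m <- vapply(tracks, track_cn, numeric(nrow(ref)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(ref))
  mins <- apply(m, 1, min)
  maxs <- apply(m, 1, max)
  data.frame(chrom = ref$chrom, start = ref$start, end = ref$end,
             min = mins, max = maxs, mean = rowMeans(m),
             range = maxs - mins, stringsAsFactors = FALSE)
}

## ------------------------------------------------------------ gene level

#' Pick each gene's longest isoform
#'
#' Per gene symbol, the transcript maximizing span (end - start); ties are
#' broken by the lexicographically smallest transcript id.
#'
#' @param models data.frame(chrom, start, end, gene, transcript).
#' @return One row per gene symbol.
#' @export
select_longest_isoform <- function(models) {
  stopifnot(all(c("chrom", "start", "end", "gene", "transcript") %in%
                names(models)))
  span <- models$end - models$start
  ord <- order(models$gene, -span, models$transcript)
  m <- models[ord, , drop = FALSE]
  out <- m[!duplicated(m$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pseudoautosomal regions of GRCh38
#'
#' PAR coordinates are a property of the reference build, shipped as
#' defaults and overridable for other builds.
#' @return data.frame(chrom, start, end), 0-based half-open.
#' @export
par_regions_grch38 <- function() {
  data.frame(chrom = c("chrX", "chrX"),
             start = c(10000L, 155701382L),
             end = c(2781479L, 156030895L),
             name = c("PAR1", "PAR2"), stringsAsFactors = FALSE)
}

# >= 1 bp half-open overlap of a gene with windows on its chromosome
intersecting_windows <- function(gene, track) {
  which(track$chrom == gene$chrom &
        track$start < gene$end & track$end > gene$start)
}

#' Gene-level copy number from a window track
#'
#' The median copy number of windows overlapping the gene by at least 1 bp.
#' Genes intersecting fewer than `min_windows` windows are excluded
#' (returned as `NA` with attribute `excluded`). For XY samples, genes lying
#' entirely in the chrX non-pseudoautosomal region are doubled prior to
#' reporting; genes straddling a PAR boundary are flagged (attribute
#' `par_boundary`) and left undoubled rather than silently mixing ploidy
#' regimes.
#'
#' @param gene A one-row data.frame (chrom, start, end).
#' @param track A `cn_track`.
#' @param sex `"XX"` or `"XY"`.
#' @param par PAR intervals for the build (default GRCh38).
#' @param chrx Name of the X chromosome sequence.
#' @param min_windows Minimum intersecting windows to report (default 3).
#' @export
gene_copy_number <- function(gene, track, sex = "XX",
                             par = par_regions_grch38(), chrx = "chrX",
                             min_windows = 3L) {
  stopifnot(sex %in% c("XX", "XY"))
  ix <- intersecting_windows(gene, track)
  n <- length(ix)
  if (n < min_windows) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    attr(out, "n_windows") <- n
    return(out)
  }
  cn <- median(track$cn[ix])
  par_boundary <- FALSE
  if (sex == "XY" && identical(gene$chrom, chrx)) {
    px <- par[par$chrom == chrx, , drop = FALSE]
    overlaps_par <- any(gene$start < px$end & gene$end > px$start)
    if (!overlaps_par) {
      cn <- 2 * cn            # nonPAR chrX is haploid in XY; rescale
    } else {
      within_par <- any(gene$start >= px$start & gene$end <= px$end)
      if (!within_par) par_boundary <- TRUE
    }
  }
  attr(cn, "n_windows") <- n
  if (par_boundary) attr(cn, "par_boundary") <- TRUE
  cn
}

#' Gene-by-sample copy-number matrix
#'
#' Selects the longest isoform per gene, drops mitochondrial genes and genes
#' intersecting fewer than `min_windows` windows, and reports per-sample
#' medians of intersecting windows with XY chrX nonPAR doubling.
#'
#' @param models Gene models data.frame(chrom, start, end, gene, transcript).
#' @param tracks Named list of `cn_track`s.
#' @param sex Named character vector ("XX"/"XY") per sample; default all XX.
#' @inheritParams gene_copy_number
#' @param exclude_chrom Chromosomes omitted from gene summaries
#'   (default `"chrM"`).
#' @return List: `genes` (the chosen isoforms with n_windows) and `cn`
#'   (gene-by-sample numeric matrix).
#' @export
gene_cn_matrix <- function(models, tracks, sex = NULL,
                           par = par_regions_grch38(), chrx = "chrX",
                           min_windows = 3L, exclude_chrom = "chrM") {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (is.null(sex)) sex <- setNames(rep("XX", length(tracks)), names(tracks))
  iso <- select_longest_isoform(models)
  iso <- iso[!(iso$chrom %in% exclude_chrom), , drop = FALSE]
  ref <- tracks[[1]]
  nw <- vapply(seq_len(nrow(iso)), function(i)
    length(intersecting_windows(iso[i, ], ref)), 0L)
  keep <- nw >= min_windows
  iso <- iso[keep, , drop = FALSE]
  iso$n_windows <- nw[keep]
  cn <- matrix(NA_real_, nrow(iso), length(tracks),
               dimnames = list(iso$gene, names(tracks)))
  for (s in names(tracks)) {
    for (i in seq_len(nrow(iso))) {
      cn[i, s] <- as.numeric(gene_copy_number(
        iso[i, ], tracks[[s]], sex = sex[[s]], par = par, chrx = chrx,
        min_windows = min_windows))
    }
  }
  list(genes = iso, cn = cn)
}

## ---------------------------------------------------------------- heatmap

# round half away from zero (cn >= 0, so floor(x + 0.5))
round_half_up <- function(x) floor(x + 0.5)

#' Heatmap color palette for integer copy numbers
#'
#' Fixed palette for integers 0..10 plus one saturation color for > 10:
#' blues below 2, white at 2, reds above.
#' @return Named character vector of `r,g,b` strings.
#' @export
cn_palette <- function() {
  c("0" = "8,48,107", "1" = "107,174,214", "2" = "247,247,247",
    "3" = "253,190,133", "4" = "253,141,60", "5" = "230,85,13",
    "6" = "217,48,31", "7" = "179,24,24", "8" = "140,10,20",
    "9" = "105,5,20", "10" = "75,0,20", ">10" = "40,0,15")
}

#' Heatmap track: copy numbers rounded to integers as colored BED9
#'
#' Rounding is half-away-from-zero (2.5 rounds to 3). The itemRgb color
#' encodes the rounded integer via [cn_palette()].
#'
#' @param track A `cn_track`.
#' @param path Optional output path.
#' @return The BED9 data.frame (invisibly if written).
#' @export
heatmap_bed <- function(track, path = NULL) {
  pal <- cn_palette()
  cni <- round_half_up(track$cn)
  key <- ifelse(cni > 10, ">10", as.character(cni))
  out <- data.frame(
    chrom = track$chrom, start = track$start, end = track$end,
    name = paste0("cn", ifelse(cni > 10, "10plus", cni)),
    score = 0L, strand = ".",
    thickStart = track$start, thickEnd = track$end,
    itemRgb = unname(pal[key]), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    return(invisible(out))
  }
  out
}

## --------------------------------------------------------------- track hub

#' Emit a UCSC track-hub directory for a set of samples
#'
#' Writes `hub.txt`, `genomes.txt` and `<genome>/trackDb.txt` with one raw
#' and one heatmap stanza per sample, grouped by population label. The
#' output passes [validate_trackhub()] (offline stanza-syntax rules: unique
#' track names, required keys). Conversion of BED payloads to bigBed for
#' actual hosting is left to external tooling.
#'
#' @param samples data.frame with columns `sample`, `population`, and paths
#'   `raw_bed`, `heatmap_bed` (referenced, not copied).
#' @param dir Output directory (created).
#' @param genome UCSC genome label (default `"hg38"`).
#' @param hub_name Hub identifier.
#' @return The hub directory path, invisibly.
#' @export
build_trackhub <- function(samples, dir, genome = "hg38",
                           hub_name = "kmercn") {
  stopifnot(is.data.frame(samples),
            all(c("sample", "population") %in% names(samples)))
  if (anyDuplicated(samples$sample))
    stop("duplicate sample names: ",
         paste(unique(samples$sample[duplicated(samples$sample)]),
               collapse = ", "))
  dir.create(file.path(dir, genome), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(paste("hub", hub_name),
               paste("shortLabel", hub_name, "CN"),
               paste("longLabel", hub_name,
                     "paralog-specific copy-number tracks"),
               "genomesFile genomes.txt",
               "email kmercn@example.org"),
             file.path(dir, "hub.txt"))
  writeLines(c(paste("genome", genome),
               paste0("trackDb ", genome, "/trackDb.txt")),
             file.path(dir, "genomes.txt"))
  stanzas <- character(0)
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]
    pop <- samples$population[i]
    raw <- if ("raw_bed" %in% names(samples)) samples$raw_bed[i]
           else paste0(s, ".cn.bed")
    heat <- if ("heatmap_bed" %in% names(samples)) samples$heatmap_bed[i]
            else paste0(s, ".heatmap.bed")
    stanzas <- c(stanzas,
      paste("track", paste0(s, "_raw")),
      paste("shortLabel", paste0(s, " CN")),
      paste("longLabel", sprintf("%s (%s) raw copy number", s, pop)),
      "type bedGraph",
      paste("bigDataUrl", raw),
      paste("group", pop),
      "visibility full",
      "",
      paste("track", paste0(s, "_heatmap")),
      paste("shortLabel", paste0(s, " CN heat")),
      paste("longLabel", sprintf("%s (%s) rounded copy-number heatmap", s, pop)),
      "type bigBed 9",
      "itemRgb on",
      paste("bigDataUrl", heat),
      paste("group", pop),
      "visibility dense",
      "")
  }
  writeLines(stanzas, file.path(dir, genome, "trackDb.txt"))
  invisible(dir)
}

#' Offline syntax validation of a track-hub directory
#'
#' Checks that hub.txt/genomes.txt exist with their required keys and that
#' every trackDb stanza has a unique `track` name plus `shortLabel`,
#' `longLabel`, `type` and `bigDataUrl` keys.
#'
#' @param dir Hub directory from [build_trackhub()].
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_trackhub <- function(dir) {
  req_file <- function(p) {
    if (!file.exists(p)) stop("missing hub file: ", p)
    readLines(p)
  }
  hub <- req_file(file.path(dir, "hub.txt"))
  for (key in c("hub ", "shortLabel ", "longLabel ", "genomesFile ", "email "))
    if (!any(startsWith(hub, key))) stop("hub.txt missing key: ", key)
  genomes <- req_file(file.path(dir, "genomes.txt"))
  if (!any(startsWith(genomes, "genome "))) stop("genomes.txt missing genome")
  tdb_rel <- sub("^trackDb ", "", grep("^trackDb ", genomes, value = TRUE))
  if (length(tdb_rel) != 1) stop("genomes.txt must name one trackDb")
  lines <- req_file(file.path(dir, tdb_rel))
  stanza_id <- cumsum(startsWith(lines, "track "))
  body <- nzchar(lines)
  names_seen <- character(0)
  for (sid in unique(stanza_id[stanza_id > 0])) {
    st <- lines[body & stanza_id == sid]
    keys <- sub(" .*", "", st)
    for (need in c("track", "shortLabel", "longLabel", "type", "bigDataUrl"))
      if (!need %in% keys)
        stop("trackDb stanza ", sid, " missing key: ", need)
    nm <- sub("^track ", "", st[startsWith(st, "track ")][1])
    if (nm %in% names_seen) stop("duplicate track name: ", nm)
    names_seen <- c(names_seen, nm)
  }
  invisible(TRUE)
}
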