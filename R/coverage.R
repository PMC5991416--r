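#' Construct a coverage track
#'
#' A coverage track is a named list of per-chromosome vectors of
#' non-negative counts at a fixed resolution (1 bp per element for
#' per-nucleotide tracks, 25 for the binned MCM analysis).
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param resolution bp per element.
#' @param sample_label free-text label (genotype + mark).
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, resolution = 1, sample_label = "") {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be a named list with unique chromosome names")
  for (cn in names(values)) {
    v <- values[[cn]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("coverage on '", cn, "' must be finite and non-negative")
  }
  structure(list(values = values, resolution = resolution,
                 sample_label = sample_label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(class(x)[1], if (nzchar(x$sample_label)) paste0("[", x$sample_label, "]"),
      ":", length(x$values), "chromosomes at", x$resolution,
      "bp resolution, total", signif(track_total(x), 6), "\n")
  invisible(x)
}

#' Total signal in a track
#' @param track a `coverage_track` or `normalized_track`.
#' @return sum over all chromosomes.
#' @export
track_total <- function(track) sum(vapply(track$values, sum, 0))

#' Per-nucleotide coverage from read intervals
#'
#' Counts, for every nucleotide, the number of reads whose interval
#' contains it. Reads are rows of (chrom, start, end), 0-based half-open.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`.
#' @param layout a [genome_layout()].
#' @param sample_label label stored on the track.
#' @return a per-nucleotide `coverage_track`.
#' @export
coverage_from_reads <- function(reads, layout, sample_label = "") {
  sizes <- layout$chrom_sizes
  bad_chrom <- which(!(reads$chrom %in% names(sizes)))
  if (length(bad_chrom))
    stop("read ", bad_chrom[1], ": unknown chromosome '",
         reads$chrom[bad_chrom[1]], "'")
  bad <- which(reads$start < 0 | reads$end <= reads$start |
                 reads$end > sizes[reads$chrom])
  if (length(bad))
    stop("read ", bad[1], " out of chromosome bounds")
  values <- lapply(names(sizes), function(cn) {
    n <- sizes[[cn]]
    r <- reads[reads$chrom == cn, , drop = FALSE]
    if (nrow(r) == 0) return(numeric(n))
    delta <- tabulate(r$start + 1L, nbins = n + 1L) -
      tabulate(r$end + 1L, nbins = n + 1L)
    cumsum(delta)[seq_len(n)]
  })
  names(values) <- names(sizes)
  coverage_track(values, resolution = 1, sample_label = sample_label)
}

#' Collate a per-nucleotide track into fixed-width bins
#'
#' Each bin holds the sum of its member positions; a final partial bin
#' holds its partial sum, so total signal is conserved at any bin size.
#'
#' @param track per-nucleotide `coverage_track`.
#' @param bin bin width in bp, default 25.
#' @return a `coverage_track` at resolution `bin`.
#' @export
bin_track <- function(track, bin = 25) {
  if (!is.numeric(bin) || length(bin) != 1 || bin <= 0 || bin != round(bin))
    stop("bin must be a positive integer")
  if (track$resolution != 1)
    stop("bin_track expects a per-nucleotide track")
  values <- lapply(track$values, function(v) {
    n <- length(v)
    nb <- ceiling(n / bin)
    cs <- c(0, cumsum(v))
    ends <- pmin(seq_len(nb) * bin, n)
    starts <- c(0, ends[-nb])
    cs[ends + 1] - cs[starts + 1]
  })
  coverage_track(values, resolution = bin, sample_label = track$sample_label)
}

## logical mask per chromosome: TRUE where masked out
.mask_vector <- function(len, chrom, mask) {
  m <- logical(len)
  if (is.null(mask) || nrow(mask) == 0) return(m)
  mm <- mask[mask$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(mm))) {
    lo <- max(0, mm$start[j]); hi <- min(len, mm$end[j])
    if (hi > lo) m[(lo + 1):hi] <- TRUE
  }
  m
}

#' Depth/breadth normalisation of a per-nucleotide track
#'
#' Each per-nucleotide count is divided by depth/breadth, where depth D
#' is the total counted signal and breadth B the number of positions
#' with non-zero signal — both computed over positions outside the
#' exclusion mask. The mean normalised value over unmasked covered
#' positions is therefore exactly 1, which defines the "0" baseline on
#' the log2 scale. Masked positions (e.g. SIR-heterochromatic domains)
#' still receive values, they just do not shape D and B.
#'
#' @param track per-nucleotide `coverage_track`.
#' @param exclusion_mask optional data.frame of (chrom, start, end)
#'   intervals excluded from the baseline, or NULL for a genome-wide
#'   baseline.
#' @param mask_label label recorded on the result; defaults to
#'   "excluded" when a mask is given, "genomewide" otherwise.
#' @return object of class `normalized_track` with fields `values`,
#'   `resolution`, `sample_label`, `baseline_mask_label`, `depth`,
#'   `breadth`.
#' @export
depth_breadth_normalize <- function(track, exclusion_mask = NULL,
                                    mask_label = NULL) {
  if (track$resolution != 1)
    stop("depth/breadth normalisation requires per-nucleotide resolution")
  if (is.null(mask_label))
    mask_label <- if (is.null(exclusion_mask)) "genomewide" else "excluded"
  D <- 0; B <- 0
  masks <- list()
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    m <- .mask_vector(length(v), cn, exclusion_mask)
    masks[[cn]] <- m
    D <- D + sum(v[!m])
    B <- B + sum(v[!m] > 0)
  }
  if (B == 0) stop("empty track: no covered positions outside the mask")
  fac <- D / B
  values <- lapply(track$values, function(v) v / fac)
  structure(list(values = values, resolution = 1,
                 sample_label = track$sample_label,
                 baseline_mask_label = mask_label,
                 depth = D, breadth = B),
            class = c("normalized_track", "coverage_track"))
}

#' Log2 ChIP/input enrichment
#'
#' Elementwise `log2((chip + pseudocount) / (input + pseudocount))` on
#' two tracks of identical resolution and chromosome structure. With
#' depth/breadth-normalised inputs, uniformly covered background sits
#' at 0.
#'
#' @param chip,input tracks (typically `normalized_track`s).
#' @param pseudocount added to both terms, in the tracks' units;
#'   default 0.5.
#' @return a `normalized_track` of log2 ratios.
#' @export
log2_enrichment <- function(chip, input, pseudocount = 0.5) {
  if (chip$resolution != input$resolution)
    stop("resolution mismatch between chip and input")
  if (!identical(names(chip$values), names(input$values)))
    stop("chromosome mismatch between chip and input")
  values <- lapply(names(chip$values), function(cn) {
    a <- chip$values[[cn]]; b <- input$values[[cn]]
    if (length(a) != length(b)) stop("length mismatch on '", cn, "'")
    log2((a + pseudocount) / (b + pseudocount))
  })
  names(values) <- names(chip$values)
  structure(list(values = values, resolution = chip$resolution,
                 sample_label = paste0("log2(", chip$sample_label, "/",
                                       input$sample_label, ")"),
                 baseline_mask_label = chip$baseline_mask_label %||% "none",
                 depth = NA_real_, breadth = NA_real_),
            class = c("normalized_track", "coverage_track"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale a track so its total matches a reference
#'
#' Multiplies every value by `sum(reference) / sum(track)`, leaving the
#' reference unchanged. Used to put samples on the common scale of the
#' no-loading (cdc6-4) background before peak comparison.
#'
#' @param track track to rescale.
#' @param reference track supplying the target total.
#' @return rescaled `coverage_track`.
#' @export
scale_to_reference <- function(track, reference) {
  if (track$resolution != reference$resolution)
    stop("resolution mismatch")
  tot <- track_total(track)
  if (tot == 0) stop("cannot scale a zero-total track")
  fac <- track_total(reference) / tot
  values <- lapply(track$values, function(v) v * fac)
  coverage_track(values, resolution = track$resolution,
                 sample_label = track$sample_label)
}

#' Write a track as bedGraph
#'
#' Runs of equal values are merged into single records.
#'
#' @param track a `coverage_track` or `normalized_track`.
#' @param path output path (".bedGraph").
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track$values), function(cn) {
    v <- track$values[[cn]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * track$resolution
    starts <- c(0, ends[-length(ends)])
    GenomicRanges::GRanges(cn, IRanges::IRanges(start = starts + 1L,
                                                end = ends),
                           score = r$values)
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a per-nucleotide track
#'
#' @param path bedGraph path.
#' @param layout a [genome_layout()]; chromosomes absent from the file
#'   get all-zero coverage.
#' @param sample_label label stored on the track.
#' @return per-nucleotide `coverage_track`.
#' @export
read_bedgraph <- function(path, layout, sample_label = "") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  sizes <- layout$chrom_sizes
  values <- lapply(names(sizes), function(cn) numeric(sizes[[cn]]))
  names(values) <- names(sizes)
  df <- as.data.frame(gr)
  for (i in seq_len(nrow(df))) {
    cn <- as.character(df$seqnames[i])
    if (!(cn %in% names(sizes)))
      stop("bedGraph record ", i, ": unknown chromosome '", cn, "'")
    values[[cn]][df$start[i]:df$end[i]] <- df$score[i]
  }
  coverage_track(values, resolution = 1, sample_label = sample_label)
}
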