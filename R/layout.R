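#' Recognised locus classes
#'
#' Loci are classified as confirmed replication origins, non-origin
#' intergenic regions carrying an ORC-site match, intergenic control
#' regions with neither, or heterochromatic loci (HM silencers, rDNA,
#' subtelomeric origins).
#'
#' @export
LOCUS_CLASSES <- c("origin", "nonorigin_orc", "intergenic_control",
                   "heterochromatic")

#' Nucleosome position labels around an ORC site
#'
#' Three nucleosomes on either side of the ORC site, numbered outward
#' from the nucleosome-depleted region.
#'
#' @export
NUC_POSITIONS <- c("-3", "-2", "-1", "+1", "+2", "+3")

#' Construct a genome layout
#'
#' A genome layout records chromosome names and sizes plus the intervals
#' established as SIR-heterochromatic domains (HM loci, rDNA, telomeric
#' zones). Coordinates are 0-based half-open throughout.
#'
#' @param chrom_sizes named numeric vector of chromosome sizes in bp;
#'   names are the chromosome identifiers.
#' @param het_intervals optional data.frame with columns `chrom`, `start`,
#'   `end` giving heterochromatin blocks.
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(chrom_sizes, het_intervals = NULL) {
  if (is.null(names(chrom_sizes)) || anyDuplicated(names(chrom_sizes)))
    stop("chrom_sizes must have unique names")
  if (any(chrom_sizes <= 0) || any(!is.finite(chrom_sizes)))
    stop("chromosome sizes must be positive and finite")
  if (is.null(het_intervals)) {
    het_intervals <- data.frame(chrom = character(), start = integer(),
                                end = integer())
  } else {
    het_intervals <- as.data.frame(het_intervals)[, c("chrom", "start", "end")]
    bad <- which(!(het_intervals$chrom %in% names(chrom_sizes)) |
                   het_intervals$start < 0 |
                   het_intervals$end <= het_intervals$start |
                   het_intervals$end > chrom_sizes[het_intervals$chrom])
    if (length(bad))
      stop("invalid heterochromatin interval at row ", bad[1])
  }
  structure(list(chrom_sizes = chrom_sizes, het_intervals = het_intervals),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_sizes), "chromosomes,",
      sum(x$chrom_sizes), "bp total,", nrow(x$het_intervals),
      "heterochromatin blocks\n")
  invisible(x)
}

#' Validate a locus table against a genome layout
#'
#' Checks coordinate sanity, class labels, and the pairing rule that
#' intergenic controls carry no ORC-site anchor while every other class
#' carries both `orc_start` and `t_rich_strand`.
#'
#' @param loci data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `locus_class`, `orc_start`, `t_rich_strand`.
#' @param layout a [genome_layout()].
#' @return the validated loci, invisibly. Errors name the offending row.
#' @export
validate_loci <- function(loci, layout) {
  need <- c("id", "chrom", "start", "end", "locus_class", "orc_start",
            "t_rich_strand")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("loci table lacks column(s): ",
                         paste(miss, collapse = ", "))
  sizes <- layout$chrom_sizes
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    if (!(l$chrom %in% names(sizes)))
      stop("row ", i, ": unknown chromosome '", l$chrom, "'")
    if (is.na(l$start) || is.na(l$end) || l$start < 0 || l$end <= l$start ||
        l$end > sizes[[l$chrom]])
      stop("row ", i, ": malformed coordinates [", l$start, ", ", l$end, ")")
    if (!(l$locus_class %in% LOCUS_CLASSES))
      stop("row ", i, ": unknown locus class '", l$locus_class, "'")
    has_orc <- !is.na(l$orc_start)
    has_strand <- !is.na(l$t_rich_strand)
    if (l$locus_class == "intergenic_control") {
      if (has_orc || has_strand)
        stop("row ", i, ": intergenic_control loci must not carry ORC fields")
    } else {
      if (!has_orc || !has_strand)
        stop("row ", i, ": class '", l$locus_class,
             "' requires orc_start and t_rich_strand")
      if (!(l$t_rich_strand %in% c("+", "-")))
        stop("row ", i, ": t_rich_strand must be '+' or '-'")
      if (l$orc_start < l$start || l$orc_start >= l$end)
        stop("row ", i, ": orc_start outside locus interval")
    }
  }
  if (anyDuplicated(loci$id))
    stop("duplicated locus id: ", loci$id[anyDuplicated(loci$id)])
  invisible(loci)
}

#' Load classified loci from a BED6+3 file
#'
#' The on-disk dialect is BED6 (chrom, start, end, name, score, strand)
#' extended with three columns: locus class, ORC-site start, and the
#' T-rich strand of the ORC site. Intergenic controls use "." for the
#' ORC columns.
#'
#' @param path path to the interval file (tab-separated, no header).
#' @param layout a [genome_layout()] used to validate every record.
#' @return data.frame of loci with columns `id`, `chrom`, `start`, `end`,
#'   `locus_class`, `orc_start`, `t_rich_strand`, in input order.
#' @export
load_loci <- function(path, layout) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "class",
                                         "orc_start", "t_strand"),
                           comment.char = "#")
  num <- function(x, what, row) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("row ", row, ": malformed ", what, " '", x, "'")
    v
  }
  n <- nrow(raw)
  loci <- data.frame(
    id = raw$name,
    chrom = raw$chrom,
    start = vapply(seq_len(n), function(i) num(raw$start[i], "start", i), 0),
    end = vapply(seq_len(n), function(i) num(raw$end[i], "end", i), 0),
    locus_class = raw$class,
    orc_start = vapply(seq_len(n), function(i) {
      if (raw$orc_start[i] == ".") NA_real_
      else num(raw$orc_start[i], "orc_start", i)
    }, 0),
    t_rich_strand = ifelse(raw$t_strand == ".", NA_character_, raw$t_strand),
    stringsAsFactors = FALSE)
  validate_loci(loci, layout)
  loci
}

#' Write classified loci as BED6+3
#'
#' Inverse of [load_loci()]: `load_loci(write_loci(x))` preserves all
#' fields exactly.
#'
#' @param loci validated loci table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  out <- data.frame(
    chrom = loci$chrom,
    start = format(loci$start, scientific = FALSE, trim = TRUE),
    end = format(loci$end, scientific = FALSE, trim = TRUE),
    name = loci$id,
    score = 0L,
    strand = ifelse(is.na(loci$t_rich_strand), ".", loci$t_rich_strand),
    class = loci$locus_class,
    orc_start = ifelse(is.na(loci$orc_start), ".",
                       format(loci$orc_start, scientific = FALSE, trim = TRUE)),
    t_strand = ifelse(is.na(loci$t_rich_strand), ".", loci$t_rich_strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## TRUE for each query interval that overlaps >=1 mask interval (>=1 bp)
.overlaps_mask <- function(chrom, start, end, mask) {
  hit <- logical(length(chrom))
  if (is.null(mask) || nrow(mask) == 0) return(hit)
  for (cn in unique(chrom)) {
    m <- mask[mask$chrom == cn, , drop = FALSE]
    sel <- chrom == cn
    if (nrow(m) == 0) next
    q <- IRanges::IRanges(start = start[sel] + 1L, end = end[sel])
    s <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Exclude heterochromatic and telomere-proximal loci
#'
#' Removes loci whose interval overlaps any heterochromatin block by at
#' least 1 bp, and loci lying within `telomere_bp` of either chromosome
#' end (distance measured from the locus interval edges). The removed
#' loci and the reason for removal are attached as attribute `"removed"`.
#'
#' @param loci validated loci table.
#' @param layout a [genome_layout()].
#' @param telomere_bp exclusion distance from chromosome ends, default
#'   15000 bp.
#' @return the surviving loci; `attr(, "removed")` is a data.frame of
#'   `id` and `reason` ("heterochromatic" or "telomeric").
#' @export
apply_heterochromatin_filter <- function(loci, layout, telomere_bp = 15000) {
  validate_loci(loci, layout)
  sizes <- layout$chrom_sizes
  het <- .overlaps_mask(loci$chrom, loci$start, loci$end,
                        layout$het_intervals)
  telo <- loci$start < telomere_bp |
    loci$end > (sizes[loci$chrom] - telomere_bp)
  keep <- !het & !telo
  removed <- data.frame(
    id = loci$id[!keep],
    reason = ifelse(het[!keep], "heterochromatic", "telomeric"))
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Orient a fragment around a locus's ORC site
#'
#' Builds the mapping from fragment offsets to genomic coordinates such
#' that offset 0 is the first nucleotide of the ORC site read along the
#' T-rich strand, and increasing offsets run 5' to 3' along that strand.
#' For a "+" T-rich strand offset x maps to `orc_start + x`; for "-" it
#' maps to `orc_start - x`. The fragment spans `2 * flank + 1` positions
#' (1201 bp at the default).
#'
#' @param locus one-row loci data.frame (or list) with `orc_start` and
#'   `t_rich_strand` present.
#' @param layout a [genome_layout()].
#' @param flank half-width in bp, default 600.
#' @param pad_missing if TRUE, offsets falling outside the chromosome
#'   are kept with `NA` genomic positions instead of raising an error.
#' @return an object of class `oriented_fragment` with fields
#'   `locus_id`, `chrom`, `strand`, `orc_start`, `flank`, `offsets`
#'   (-flank..flank) and `pos` (0-based genomic coordinate per offset).
#' @export
orient_fragment <- function(locus, layout, flank = 600, pad_missing = FALSE) {
  if (is.na(locus$orc_start) || is.na(locus$t_rich_strand))
    stop("locus '", locus$id, "' lacks an ORC-site anchor")
  size <- layout$chrom_sizes[[locus$chrom]]
  offsets <- seq.int(-flank, flank)
  sgn <- if (locus$t_rich_strand == "+") 1L else -1L
  pos <- locus$orc_start + sgn * offsets
  oob <- pos < 0 | pos >= size
  if (any(oob)) {
    if (!pad_missing)
      stop("fragment for locus '", locus$id,
           "' extends past the chromosome boundary")
    pos[oob] <- NA_real_
  }
  structure(list(locus_id = locus$id, chrom = locus$chrom,
                 strand = locus$t_rich_strand,
                 orc_start = locus$orc_start, flank = flank,
                 offsets = offsets, pos = pos),
            class = "oriented_fragment")
}

#' Orient fragments for a set of loci
#'
#' Applies [orient_fragment()] to every locus that carries an ORC-site
#' anchor. Fragments that would cross a chromosome end are dropped by
#' default (recorded in attribute `"removed"`); with
#' `pad_missing = TRUE` they are kept with missing positions.
#'
#' @inheritParams orient_fragment
#' @param loci validated loci table.
#' @return named list of `oriented_fragment` objects keyed by locus id.
#' @export
orient_fragments <- function(loci, layout, flank = 600, pad_missing = FALSE) {
  anch <- loci[!is.na(loci$orc_start), , drop = FALSE]
  out <- list(); dropped <- character()
  for (i in seq_len(nrow(anch))) {
    fr <- tryCatch(orient_fragment(anch[i, ], layout, flank, pad_missing),
                   error = function(e) NULL)
    if (is.null(fr)) dropped <- c(dropped, anch$id[i])
    else out[[anch$id[i]]] <- fr
  }
  attr(out, "removed") <- dropped
  out
}
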