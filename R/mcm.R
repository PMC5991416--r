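## centered rolling mean with truncated windows at the ends
.rollmean <- function(v, k) {
  if (k <= 1) return(v)
  n <- length(v)
  hl <- (k - 1L) %/% 2L
  hr <- k - 1L - hl
  i <- seq_len(n)
  lo <- pmax(i - hl, 1L); hi <- pmin(i + hr, n)
  cs <- c(0, cumsum(v))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Call the top-N peaks from a binned track
#'
#' Smooths each chromosome with a centred rolling mean, takes local
#' maxima above the genome-wide median of the smoothed signal as seeds,
#' merges seeds closer than `merge_bp`, scores each merged peak by the
#' summed smoothed signal over its span, and returns the `n`
#' highest-scoring peaks (rank 1 = highest). Ties are broken by
#' chromosome name then leftmost coordinate, so rankings are
#' deterministic and invariant to positive rescaling of the track.
#'
#' @param track binned `coverage_track`.
#' @param n number of peaks to keep, default 400 (fewer are returned if
#'   fewer exist).
#' @param smooth_bins rolling-mean window in bins, default 3.
#' @param merge_bp seeds within this genomic distance merge, default 500.
#' @return data.frame of class `peak_set` with columns `rank`, `chrom`,
#'   `start`, `end`, `score`; attribute `n_requested`.
#' @export
call_top_peaks <- function(track, n = 400, smooth_bins = 3, merge_bp = 500) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0)
    stop("n must be a positive integer")
  res <- track$resolution
  smoothed <- lapply(track$values, .rollmean, k = smooth_bins)
  med <- stats::median(unlist(smoothed, use.names = FALSE))
  peaks <- list()
  for (cn in names(smoothed)) {
    s <- smoothed[[cn]]
    nb <- length(s)
    if (nb == 0) next
    left <- c(-Inf, s[-nb]); right <- c(s[-1], -Inf)
    seeds <- which(s > med & s >= left & s >= right)
    if (!length(seeds)) next
    seed_pos <- (seeds - 1L) * res
    grp <- cumsum(c(1, diff(seed_pos) > merge_bp))
    for (g in unique(grp)) {
      sg <- seeds[grp == g]
      first <- min(sg); last <- max(sg)
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = cn,
        start = (first - 1L) * res,
        end = last * res,
        score = sum(s[first:last]))
    }
  }
  if (!length(peaks)) {
    out <- data.frame(rank = integer(), chrom = character(),
                      start = numeric(), end = numeric(), score = numeric())
  } else {
    pk <- do.call(rbind, peaks)
    ord <- order(-pk$score, pk$chrom, pk$start)
    pk <- pk[ord, , drop = FALSE]
    pk <- utils::head(pk, n)
    out <- cbind(rank = seq_len(nrow(pk)), pk)
    rownames(out) <- NULL
  }
  attr(out, "n_requested") <- n
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Write a peak set as BED with the score column
#' @param peaks a `peak_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.frame(chrom = peaks$chrom,
                    start = format(peaks$start, scientific = FALSE, trim = TRUE),
                    end = format(peaks$end, scientific = FALSE, trim = TRUE),
                    name = paste0("peak_", peaks$rank),
                    score = peaks$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## per-peak logical: overlaps >= 1 locus interval
.peak_hits <- function(peaks, loci) {
  .overlaps_mask(peaks$chrom, peaks$start, peaks$end,
                 data.frame(chrom = loci$chrom, start = loci$start,
                            end = loci$end))
}

#' Origin ids identified by a peak set
#'
#' Loci whose interval overlaps at least one peak. Used to turn a top-N
#' peak list into the set of confirmed origins it identifies.
#'
#' @param peaks a `peak_set`.
#' @param loci loci table (typically origins).
#' @return character vector of locus ids.
#' @export
origins_identified <- function(peaks, loci) {
  hit <- .overlaps_mask(loci$chrom, loci$start, loci$end,
                        data.frame(chrom = peaks$chrom, start = peaks$start,
                                   end = peaks$end))
  loci$id[hit]
}

#' Origin-overlap saturation across peak-rank bins
#'
#' Divides ranked peaks into consecutive blocks (default 100 peaks per
#' block, as used to calibrate how many top peaks mark confirmed
#' origins) and reports the percent of peaks in each block overlapping
#' at least one origin.
#'
#' @param peaks a ranked `peak_set`.
#' @param origins origin loci table.
#' @param bin_peaks peaks per block, default 100.
#' @return data.frame with `block`, `from_rank`, `to_rank`, `n_peaks`,
#'   `percent_overlapping`.
#' @export
peak_origin_saturation <- function(peaks, origins, bin_peaks = 100) {
  if (nrow(peaks) == 0)
    return(data.frame(block = integer(), from_rank = integer(),
                      to_rank = integer(), n_peaks = integer(),
                      percent_overlapping = numeric()))
  hit <- .peak_hits(peaks, origins)
  block <- ceiling(peaks$rank / bin_peaks)
  agg <- lapply(sort(unique(block)), function(b) {
    sel <- block == b
    data.frame(block = b,
               from_rank = min(peaks$rank[sel]),
               to_rank = max(peaks$rank[sel]),
               n_peaks = sum(sel),
               percent_overlapping = 100 * mean(hit[sel]))
  })
  do.call(rbind, agg)
}

#' Overlap statistics between two origin id sets
#'
#' Percent overlap is computed against the smaller set, the only
#' denominator under which 330 shared origins out of 338 and 340 give
#' the reported >97%.
#'
#' @param origin_ids_a,origin_ids_b character vectors of origin ids.
#' @return list with `n_a`, `n_b`, `n_common`, `percent`.
#' @export
set_overlap_stats <- function(origin_ids_a, origin_ids_b) {
  a <- unique(origin_ids_a); b <- unique(origin_ids_b)
  if (min(length(a), length(b)) == 0)
    stop("overlap percentage undefined: one set is empty")
  common <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_common = common,
       percent = 100 * common / min(length(a), length(b)))
}

#' Fraction of otherwise-defective origins rescued without SIR2
#'
#' Given the origins identified in the rescue genotype (cdc6-4 sir2del)
#' and in the two loading-proficient genotypes, reports how many of the
#' rescued origins fall in the union of the proficient sets, as a
#' percent of the proficient core (their intersection).
#'
#' @param rescued_ids origin ids from the rescue genotype's top peaks.
#' @param wt_ids,sir2_ids origin ids from the two proficient genotypes.
#' @return list with `n_rescued_in_union`, `core`, `percent`.
#' @export
rescue_fraction <- function(rescued_ids, wt_ids, sir2_ids) {
  core <- intersect(unique(wt_ids), unique(sir2_ids))
  if (length(core) == 0) stop("empty core: wt and sir2 sets do not intersect")
  in_union <- length(intersect(unique(rescued_ids),
                               union(wt_ids, sir2_ids)))
  list(n_rescued_in_union = in_union, core = length(core),
       percent = 100 * in_union / length(core))
}

#' Define per-origin signal windows from a reference peak set
#'
#' For each origin, the window is the union of the origin interval and
#' any overlapping reference-genotype peak spans, padded by `pad` bp and
#' clamped to the chromosome. The same window is then reused verbatim
#' across genotypes so signal areas are comparable.
#'
#' @param peaks reference `peak_set` (wild type).
#' @param origins origin loci table.
#' @param layout a [genome_layout()].
#' @param pad padding in bp, default 250.
#' @return data.frame with `id`, `chrom`, `start`, `end`.
#' @export
define_origin_windows <- function(peaks, origins, layout, pad = 250) {
  sizes <- layout$chrom_sizes
  out <- origins[, c("id", "chrom", "start", "end")]
  for (i in seq_len(nrow(out))) {
    sel <- peaks$chrom == out$chrom[i] &
      peaks$start < out$end[i] & peaks$end > out$start[i]
    if (any(sel)) {
      out$start[i] <- min(out$start[i], peaks$start[sel])
      out$end[i] <- max(out$end[i], peaks$end[sel])
    }
    out$start[i] <- max(0, out$start[i] - pad)
    out$end[i] <- min(sizes[[out$chrom[i]]], out$end[i] + pad)
  }
  out
}

#' Signal area over a genomic window
#'
#' Sums track values over all bins overlapping `[start, end)`.
#'
#' @param track a `coverage_track` (any resolution).
#' @param chrom,start,end window coordinates (0-based half-open).
#' @return numeric area.
#' @export
origin_signal <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome '", chrom, "'")
  res <- track$resolution
  if (start < 0 || end > length(v) * res || end <= start)
    stop("window [", start, ", ", end, ") outside chromosome '", chrom, "'")
  b0 <- floor(start / res) + 1L
  b1 <- ceiling(end / res)
  sum(v[b0:b1])
}

#' Signal areas for many windows across genotype tracks
#'
#' @param tracks named list of `coverage_track`s (one per genotype).
#' @param windows data.frame from [define_origin_windows()].
#' @return data.frame with `id` and one signal column per track.
#' @export
origin_signals <- function(tracks, windows) {
  out <- data.frame(id = windows$id)
  for (g in names(tracks)) {
    out[[g]] <- vapply(seq_len(nrow(windows)), function(i)
      origin_signal(tracks[[g]], windows$chrom[i], windows$start[i],
                    windows$end[i]), 0)
  }
  out
}

#' Genome-wide background level of a track
#'
#' The median bin value, a robust estimate of the non-peak noise floor
#' when peaks occupy a minority of the genome.
#'
#' @param track a `coverage_track`.
#' @return median value per bin.
#' @export
track_background_level <- function(track) {
  stats::median(unlist(track$values, use.names = FALSE))
}

#' Estimate the rescued fraction of origins
#'
#' Classifies each origin as rescued when its background-subtracted
#' responsiveness ratio exceeds a cutoff. For each genotype the
#' expected background area in a window is the cdc6-4 (no detectable
#' loading) area rescaled by the ratio of genome-wide background levels
#' ([track_background_level()]), which makes the subtraction insensitive
#' to how the samples were depth-scaled; non-rescued origins then sit
#' near ratio 0 regardless of window size. The cutoff mirrors the
#' dotted-line threshold separating plasmid-validated responsive origins
#' in the chromosomal ranking; it is a tunable with no asserted
#' canonical value.
#'
#' @param tracks named list of binned `coverage_track`s containing at
#'   least `sir2d`, `cdc64` and `cdc64_sir2d`.
#' @param windows per-origin windows from [define_origin_windows()].
#' @param cutoff ratio above which an origin counts as rescued,
#'   default 0.05.
#' @return list with `fraction` (of origins with a defined ratio), `n`,
#'   `n_rescued`, `cutoff`, and the per-origin `ratio` vector (named by
#'   origin id).
#' @export
estimate_rescued_fraction <- function(tracks, windows, cutoff = 0.05) {
  need <- c("sir2d", "cdc64", "cdc64_sir2d")
  if (!all(need %in% names(tracks)))
    stop("tracks must include ", paste(need, collapse = ", "))
  sg <- origin_signals(tracks[need], windows)
  bg <- vapply(tracks[need], track_background_level, 0)
  adj <- function(genotype)
    pmax(sg[[genotype]] - sg$cdc64 * bg[[genotype]] / bg[["cdc64"]], 0)
  num <- adj("cdc64_sir2d"); den <- adj("sir2d")
  ok <- den > 0
  if (!any(ok)) stop("no origin has positive background-subtracted signal")
  ratio <- stats::setNames(num[ok] / den[ok], sg$id[ok])
  list(fraction = mean(ratio > cutoff), n = sum(ok),
       n_rescued = sum(ratio > cutoff), cutoff = cutoff, ratio = ratio)
}

#' SIR2-responsiveness table with quintile stratification
#'
#' The responsiveness of an origin is the ratio of its MCM signal in
#' cdc6-4 sir2del cells to that in sir2del cells; a ratio near 1 means
#' loss of SIR2 fully rescued MCM loading at that origin. Origins are
#' ranked by the ratio (rank 1 = most responsive) and divided into
#' quintiles whose sizes differ by at most one; quintile 5 holds the
#' highest ratios. Groups low/medium/high are quintiles 1/3/5. Origins
#' with non-positive sir2del signal are excluded (attribute
#' `"excluded"`); ties are broken by locus id so the result does not
#' depend on input order.
#'
#' @param signals data.frame with columns `id`, `wt`, `sir2d`, `cdc64`,
#'   `cdc64_sir2d` of per-origin signal areas.
#' @return data.frame of class `responsiveness_table` with `ratio`,
#'   `rank`, `quintile`, `group` added, sorted by rank.
#' @export
responsiveness_table <- function(signals) {
  need <- c("id", "wt", "sir2d", "cdc64", "cdc64_sir2d")
  miss <- setdiff(need, names(signals))
  if (length(miss)) stop("signals lacks column(s): ",
                         paste(miss, collapse = ", "))
  ok <- signals$sir2d > 0
  if (!any(ok)) stop("all sir2d signals are non-positive; ratios undefined")
  excluded <- signals$id[!ok]
  s <- signals[ok, , drop = FALSE]
  s$ratio <- s$cdc64_sir2d / s$sir2d
  ord <- order(-s$ratio, s$id)
  s <- s[ord, , drop = FALSE]
  n <- nrow(s)
  s$rank <- seq_len(n)
  rank_asc <- n - s$rank + 1L
  s$quintile <- as.integer(ceiling(5 * rank_asc / n))
  s$group <- c("low", "other", "medium", "other", "high")[s$quintile]
  rownames(s) <- NULL
  attr(s, "excluded") <- excluded
  class(s) <- c("responsiveness_table", "data.frame")
  s
}
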