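## nucleosome core-particle window around a dyad: [dyad - 73, dyad + 74)
.nuc_window <- function(dyad) c(dyad - 73, dyad + 74)

## sum of a per-nucleotide track over [lo, hi), NA if outside chromosome
.window_sum <- function(track, chrom, lo, hi) {
  v <- track$values[[chrom]]
  if (is.null(v) || lo < 0 || hi > length(v)) return(NA_real_)
  sum(v[(lo + 1):hi])
}

#' Assign the six proximal nucleosomes to an oriented fragment
#'
#' Dyads falling inside the fragment are converted to offsets along the
#' T-rich strand. The three dyads with the largest negative offsets
#' (nearest the ORC site first) become positions -1, -2, -3 and the
#' three with the smallest positive offsets become +1, +2, +3;
#' unfillable slots are NA.
#'
#' @param fragment an `oriented_fragment`.
#' @param dyads data.frame with columns `chrom`, `dyad` (0-based bp),
#'   or a numeric vector of dyads on the fragment's chromosome.
#' @return named numeric vector of genomic dyad positions, names
#'   `c("-3","-2","-1","+1","+2","+3")`; NA where missing.
#' @export
assign_nucleosomes <- function(fragment, dyads) {
  if (is.data.frame(dyads))
    dyads <- dyads$dyad[dyads$chrom == fragment$chrom]
  sgn <- if (fragment$strand == "+") 1 else -1
  off <- sgn * (dyads - fragment$orc_start)
  keep <- abs(off) <= fragment$flank & off != 0
  off <- off[keep]; d <- dyads[keep]
  out <- stats::setNames(rep(NA_real_, 6), NUC_POSITIONS)
  neg <- order(-off[off < 0])             # nearest (largest, i.e. least
  dn <- d[off < 0][neg]                   # negative) first
  pos <- order(off[off > 0])
  dp <- d[off > 0][pos]
  for (k in 1:3) {
    if (k <= length(dn)) out[[paste0("-", k)]] <- dn[k]
    if (k <= length(dp)) out[[paste0("+", k)]] <- dp[k]
  }
  out
}

#' Mark/denominator ratio over one nucleosome
#'
#' Ratio of summed mark signal to summed denominator signal (input or
#' occupancy) over the 147-bp core-particle window centred on the dyad.
#'
#' @param mark,denom per-nucleotide `coverage_track`s.
#' @param chrom chromosome of the nucleosome.
#' @param dyad dyad position (0-based bp).
#' @return the ratio, or NA when the denominator window sums to zero or
#'   the window leaves the chromosome.
#' @export
nucleosome_mark_ratio <- function(mark, denom, chrom, dyad) {
  w <- .nuc_window(dyad)
  num <- .window_sum(mark, chrom, w[1], w[2])
  den <- .window_sum(denom, chrom, w[1], w[2])
  if (is.na(num) || is.na(den) || den <= 0) return(NA_real_)
  num / den
}

## per-control-locus nucleosome ratios: n_nuc contiguous dyads whose run
## centre is closest to the locus midpoint
.control_locus_ratios <- function(locus, dyads, mark, denom, n_nuc = 6) {
  d <- sort(dyads$dyad[dyads$chrom == locus$chrom])
  d <- d[d - 73 >= locus$start & d + 74 <= locus$end]
  if (length(d) == 0) return(numeric(0))
  if (length(d) > n_nuc) {
    mid <- (locus$start + locus$end) / 2
    k <- length(d) - n_nuc + 1
    centres <- vapply(seq_len(k), function(i) mean(d[i:(i + n_nuc - 1)]), 0)
    i0 <- which.min(abs(centres - mid))
    d <- d[i0:(i0 + n_nuc - 1)]
  }
  r <- vapply(d, function(x) nucleosome_mark_ratio(mark, denom, locus$chrom, x),
              0)
  r[!is.na(r)]
}

#' Baseline mark level from intergenic control loci
#'
#' For each control locus the mark/denominator ratio is averaged over
#' (up to) six contiguous nucleosomes, and these per-locus means are
#' averaged into a single scalar. Every nucleosome assessed elsewhere is
#' then normalised to this one value.
#'
#' @param control_loci loci of class `intergenic_control`.
#' @param dyads nucleosome dyad table (`chrom`, `dyad`).
#' @param mark,denom per-nucleotide tracks.
#' @param n_nuc nucleosomes per control locus, default 6.
#' @return scalar baseline; attribute `"pool"` carries all individual
#'   control nucleosome ratios.
#' @export
control_baseline <- function(control_loci, dyads, mark, denom, n_nuc = 6) {
  per_locus <- lapply(seq_len(nrow(control_loci)), function(i)
    .control_locus_ratios(control_loci[i, ], dyads, mark, denom, n_nuc))
  means <- vapply(per_locus, function(r)
    if (length(r)) mean(r) else NA_real_, 0)
  if (all(is.na(means)))
    stop("no control locus yields a resolvable nucleosome ratio")
  baseline <- mean(means, na.rm = TRUE)
  attr(baseline, "pool") <- unlist(per_locus, use.names = FALSE)
  baseline
}

#' Log2-normalise a raw ratio matrix to the control baseline
#'
#' Entries become `log2(entry / baseline)`; missing entries stay
#' missing, and non-positive entries become missing.
#'
#' @param values numeric matrix of raw mark ratios (loci x positions).
#' @param baseline positive scalar from [control_baseline()].
#' @return matrix of log2 normalised values.
#' @export
normalize_profile <- function(values, baseline) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be a positive scalar")
  values[!is.na(values) & values <= 0] <- NA_real_
  log2(values / baseline)
}

## pooled-variance two-sample t, two-sided
.pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  df <- nx + ny - 2
  ss <- sum((x - mx)^2) + sum((y - my)^2)
  degenerate <- FALSE
  if (ss == 0) {
    if (mx == my) { t <- 0; p <- 1 }
    else { t <- sign(mx - my) * Inf; p <- 0; degenerate <- TRUE }
  } else {
    sp2 <- ss / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    t <- (mx - my) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Per-position group summary with Student's t against the control pool
#'
#' For each nucleosome position, the group's non-missing log2 values are
#' summarised (n, mean, standard error) and compared to the pooled
#' control nucleosome values by a classic pooled-variance two-sample
#' Student's t-test, two-sided. Welch's unequal-variance test is
#' available via `welch = TRUE`.
#'
#' @param matrix log2-normalised profile matrix (loci x positions, from
#'   [normalize_profile()]), rownames = locus ids.
#' @param group_ids locus ids (rownames) belonging to the group.
#' @param control_pool numeric vector of log2-normalised control
#'   nucleosome values.
#' @param group_label label stored in the result.
#' @param welch use Welch's t instead of the pooled-variance test.
#' @return data.frame with `position`, `n`, `mean`, `se`, `t`, `df`,
#'   `p`, `degenerate`, `group`.
#' @export
group_profile <- function(matrix, group_ids, control_pool,
                          group_label = "group", welch = FALSE) {
  sub <- matrix[rownames(matrix) %in% group_ids, , drop = FALSE]
  rows <- lapply(colnames(sub), function(pos) {
    x <- sub[, pos]; x <- x[!is.na(x)]
    if (length(x) < 2)
      return(data.frame(position = pos, n = length(x),
                        mean = if (length(x)) mean(x) else NA_real_,
                        se = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, degenerate = NA, group = group_label))
    if (welch) {
      ht <- stats::t.test(x, control_pool, var.equal = FALSE)
      tt <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, degenerate = FALSE)
    } else {
      tt <- .pooled_t(x, control_pool)
    }
    data.frame(position = pos, n = length(x), mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)),
               t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
               group = group_label)
  })
  out <- do.call(rbind, rows)
  out$position <- factor(out$position, levels = NUC_POSITIONS)
  out
}

#' Box-and-whisker summary per position and group
#'
#' Median and quartiles use linear interpolation (quantile type 7);
#' whiskers extend to the most extreme values within 1.5 IQR of the
#' quartiles, clamped to the data range.
#'
#' @param matrix log2-normalised profile matrix.
#' @param groups named character vector or factor mapping rownames of
#'   `matrix` to group labels.
#' @return data.frame with `group`, `position`, `n`, `median`, `q1`,
#'   `q3`, `whisker_lo`, `whisker_hi`.
#' @export
boxplot_summary <- function(matrix, groups) {
  groups <- groups[rownames(matrix)]
  rows <- list()
  for (g in unique(stats::na.omit(groups))) {
    sub <- matrix[!is.na(groups) & groups == g, , drop = FALSE]
    for (pos in colnames(sub)) {
      x <- sub[, pos]; x <- x[!is.na(x)]
      if (!length(x)) next
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, position = pos, n = length(x),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
        whisker_hi = max(x[x <= q[3] + 1.5 * iqr]))
    }
  }
  do.call(rbind, rows)
}

#' Build a nucleosome-resolved mark profile around ORC sites
#'
#' End-to-end constructor: orients fragments for every ORC-anchored
#' locus, assigns the six proximal nucleosomes from the dyad table,
#' computes mark/denominator ratios, derives the intergenic-control
#' baseline, and log2-normalises everything to it.
#'
#' @param loci validated (and typically heterochromatin-filtered) loci;
#'   ORC-anchored classes are profiled, `intergenic_control` loci define
#'   the baseline.
#' @param dyads nucleosome dyad table (`chrom`, `dyad`).
#' @param mark,denom per-nucleotide tracks (e.g. H4K16ac ChIP and input).
#' @param layout a [genome_layout()].
#' @param flank fragment half-width, default 600 bp.
#' @return object of class `nuc_profile`: list with `raw` and
#'   `normalized` matrices (loci x positions), `baseline`,
#'   `control_pool` (log2-normalised control nucleosome values), and
#'   `loci` (the profiled subset).
#' @export
build_nuc_profile <- function(loci, dyads, mark, denom, layout, flank = 600) {
  anchored <- loci[loci$locus_class %in% c("origin", "nonorigin_orc"), ,
                   drop = FALSE]
  controls <- loci[loci$locus_class == "intergenic_control", , drop = FALSE]
  if (nrow(controls) == 0) stop("no intergenic_control loci for the baseline")
  frags <- orient_fragments(anchored, layout, flank = flank)
  raw <- matrix(NA_real_, nrow = length(frags), ncol = 6,
                dimnames = list(names(frags), NUC_POSITIONS))
  for (id in names(frags)) {
    dy <- assign_nucleosomes(frags[[id]], dyads)
    for (pos in NUC_POSITIONS) {
      if (!is.na(dy[[pos]]))
        raw[id, pos] <- nucleosome_mark_ratio(mark, denom,
                                              frags[[id]]$chrom, dy[[pos]])
    }
  }
  baseline <- control_baseline(controls, dyads, mark, denom)
  pool_raw <- attr(baseline, "pool")
  baseline <- as.numeric(baseline)
  normalized <- normalize_profile(raw, baseline)
  control_pool <- log2(pool_raw[pool_raw > 0] / baseline)
  structure(list(raw = raw, normalized = normalized, baseline = baseline,
                 control_pool = control_pool,
                 loci = anchored[match(rownames(raw), anchored$id), ]),
            class = "nuc_profile")
}
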