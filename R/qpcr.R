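#' Copy number from a Ct pair by the 2^-dCt method
#'
#' `2^-(ct_target - ct_ref)` against a single-copy reference locus
#' estimates the average copy number of the target: equal Ct values give
#' 1.0, and each cycle of earlier amplification doubles the estimate.
#' Assumes ideal primer efficiency. Vectorised.
#'
#' @param ct_target threshold cycle(s) of the target locus.
#' @param ct_ref threshold cycle(s) of the single-copy reference.
#' @return enrichment (predicted copy number), always positive.
#' @export
copy_number <- function(ct_target, ct_ref) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref)))
    stop("Ct values must be finite")
  2^-(ct_target - ct_ref)
}

#' Replicate-wise copy-number estimates from a well table
#'
#' For each sample (biological replicate series) and target, the dCt is
#' taken within each replicate against that replicate's reference well,
#' converted with [copy_number()], then summarised by the mean and
#' standard error across replicates. Within-replicate differencing makes
#' the estimates invariant to per-replicate plate shifts.
#'
#' @param wells data.frame with columns `sample_id`, `target`,
#'   `replicate`, `ct`.
#' @param ref_label target label of the single-copy reference locus,
#'   default "RIM15".
#' @return data.frame with `sample_id`, `target`, `n`, `mean_enrichment`,
#'   `se`.
#' @export
replicate_summary <- function(wells, ref_label = "RIM15") {
  need <- c("sample_id", "target", "replicate", "ct")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop("wells lacks column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (s in unique(wells$sample_id)) {
    ws <- wells[wells$sample_id == s, , drop = FALSE]
    ref <- ws[ws$target == ref_label, , drop = FALSE]
    if (nrow(ref) == 0)
      stop("sample '", s, "': no reference wells for '", ref_label, "'")
    ref_ct <- stats::setNames(ref$ct, ref$replicate)
    for (tg in setdiff(unique(ws$target), ref_label)) {
      wt <- ws[ws$target == tg, , drop = FALSE]
      if (any(!(wt$replicate %in% names(ref_ct))))
        stop("sample '", s, "', target '", tg,
             "': replicate without a matching reference well")
      enr <- copy_number(wt$ct, ref_ct[as.character(wt$replicate)])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, target = tg, n = length(enr),
        mean_enrichment = mean(enr),
        se = if (length(enr) > 1) stats::sd(enr) / sqrt(length(enr)) else 0)
    }
  }
  do.call(rbind, rows)
}

#' Fold change in mean enrichment between two samples
#'
#' @param estimates output of [replicate_summary()].
#' @param sample_a,sample_b sample ids (numerator, denominator).
#' @param target target label.
#' @return ratio of mean enrichments.
#' @export
fold_change <- function(estimates, sample_a, sample_b, target) {
  pick <- function(s) {
    v <- estimates$mean_enrichment[estimates$sample_id == s &
                                     estimates$target == target]
    if (length(v) != 1) stop("no unique estimate for sample '", s,
                             "', target '", target, "'")
    v
  }
  pick(sample_a) / pick(sample_b)
}

#' Simulate a qPCR well table with known copy numbers
#'
#' Per replicate, the reference Ct is drawn around a base cycle and each
#' target's Ct is `ct_ref - log2(copies) + Normal(0, noise_sd)`, so the
#' 2^-dCt estimate recovers `copies` exactly at zero noise.
#'
#' @param copy_numbers named numeric vector of true copy numbers per
#'   target (all > 0).
#' @param noise_sd Ct noise standard deviation in cycles, default 0.2.
#' @param replicates biological replicates (colonies), default 3.
#' @param seed mandatory RNG seed.
#' @param sample_id sample label, default "strain1".
#' @param ref_label reference target label, default "RIM15".
#' @param base_ct nominal reference threshold cycle, default 22.
#' @return wells data.frame (`sample_id`, `target`, `replicate`, `ct`)
#'   suitable for [replicate_summary()].
#' @export
simulate_qpcr <- function(copy_numbers, noise_sd = 0.2, replicates = 3,
                          seed, sample_id = "strain1", ref_label = "RIM15",
                          base_ct = 22) {
  if (missing(seed)) stop("a seed is required")
  if (any(copy_numbers <= 0)) stop("copy numbers must be positive")
  .with_seed(seed, {
    rows <- list()
    for (r in seq_len(replicates)) {
      ct_ref <- stats::rnorm(1, base_ct, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, target = ref_label, replicate = r, ct = ct_ref)
      for (tg in names(copy_numbers)) {
        ct <- ct_ref - log2(copy_numbers[[tg]]) + stats::rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, target = tg, replicate = r, ct = ct)
      }
    }
    do.call(rbind, rows)
  })
}
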