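#' Per-locus signal matrix over oriented fragments
#'
#' Extracts the per-nucleotide signal at every fragment offset, giving a
#' loci x offsets matrix (columns -flank..+flank). Offsets whose genomic
#' position is missing (padded fragments) are NA.
#'
#' @param signal per-nucleotide track (typically a log2
#'   `normalized_track`).
#' @param fragments list of `oriented_fragment`s (see
#'   [orient_fragments()]).
#' @return numeric matrix, rownames = locus ids, colnames = offsets.
#' @export
profile_matrix <- function(signal, fragments) {
  if (length(fragments) == 0) stop("empty fragment list")
  offs <- fragments[[1]]$offsets
  m <- matrix(NA_real_, nrow = length(fragments), ncol = length(offs),
              dimnames = list(vapply(fragments, `[[`, "", "locus_id"),
                              as.character(offs)))
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    v <- signal$values[[fr$chrom]]
    ok <- !is.na(fr$pos)
    m[i, ok] <- v[fr$pos[ok] + 1L]
  }
  m
}

#' Meta-profile of signal over oriented fragments
#'
#' Per-offset mean of the signal across loci over the 2*flank+1
#' positions of the oriented fragments (1201 bp at the default flank),
#' with missing positions excluded from that offset's mean.
#'
#' @inheritParams profile_matrix
#' @param group_label label stored on the profile.
#' @return data.frame of class `meta_profile` with `offset`, `mean`,
#'   `n`, `group`; attribute `baseline_mask_label` propagated from the
#'   signal track.
#' @export
meta_profile <- function(signal, fragments, group_label = "all") {
  m <- profile_matrix(signal, fragments)
  out <- data.frame(offset = as.integer(colnames(m)),
                    mean = colMeans(m, na.rm = TRUE),
                    n = colSums(!is.na(m)),
                    group = group_label)
  rownames(out) <- NULL
  out$mean[out$n == 0] <- NA_real_
  attr(out, "baseline_mask_label") <- signal$baseline_mask_label %||% "none"
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Meta-profiles per locus group
#'
#' @inheritParams meta_profile
#' @param groups named character vector or factor mapping locus ids to
#'   group labels (e.g. locus class, or responsiveness low/medium/high).
#'   Loci without a label are skipped.
#' @return named list of `meta_profile`s, one per non-empty group; empty
#'   groups are omitted with a warning.
#' @export
grouped_meta_profiles <- function(signal, fragments, groups) {
  ids <- vapply(fragments, `[[`, "", "locus_id")
  lev <- unique(stats::na.omit(as.character(groups)))
  out <- list()
  for (g in lev) {
    sel <- ids %in% names(groups)[!is.na(groups) & groups == g]
    if (!any(sel)) {
      warning("group '", g, "' has no fragments; omitted")
      next
    }
    out[[g]] <- meta_profile(signal, fragments[sel], group_label = g)
  }
  out
}

## evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomly repartition loci into k groups of given sizes
#'
#' Uniformly random label permutation, reproducible under `seed`. Used
#' as the negative control that destroys any planted ordering between
#' responsiveness groups.
#'
#' @param ids locus ids to partition.
#' @param k number of groups, default 3.
#' @param seed mandatory RNG seed.
#' @param sizes optional integer vector of group sizes (must sum to
#'   `length(ids)`); near-equal sizes by default.
#' @param labels group labels, default `rand1..randk` or the names of
#'   `sizes`.
#' @return named character vector: group label per locus id.
#' @export
randomized_groups <- function(ids, k = 3, seed, sizes = NULL, labels = NULL) {
  if (missing(seed)) stop("a seed is required for randomization")
  n <- length(ids)
  if (is.null(sizes)) {
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  if (length(sizes) != k || sum(sizes) != n)
    stop("sizes must have length k and sum to length(ids)")
  if (is.null(labels)) {
    labels <- if (!is.null(names(sizes))) names(sizes) else
      paste0("rand", seq_len(k))
  }
  lab <- rep(labels, times = sizes)
  perm <- .with_seed(seed, sample.int(n))
  stats::setNames(lab, ids[perm])[ids]
}

#' Mean signal over a central offset window
#'
#' @param profile a `meta_profile` (or its data.frame).
#' @param window integer length-2 vector of offsets, default
#'   `c(-200, 200)` (about one nucleosome on either side of the ORC
#'   site).
#' @return mean of the per-offset means inside the window.
#' @export
central_mean <- function(profile, window = c(-200, 200)) {
  sel <- profile$offset >= window[1] & profile$offset <= window[2]
  mean(profile$mean[sel], na.rm = TRUE)
}

#' Per-locus central signal means
#'
#' Row means of the profile matrix over a central offset window; the
#' cheap per-locus statistic used for permutation controls.
#'
#' @inheritParams profile_matrix
#' @param window central offset window, default `c(-200, 200)`.
#' @return named numeric vector, one value per locus.
#' @export
central_locus_means <- function(signal, fragments, window = c(-200, 200)) {
  m <- profile_matrix(signal, fragments)
  offs <- as.integer(colnames(m))
  rowMeans(m[, offs >= window[1] & offs <= window[2], drop = FALSE],
           na.rm = TRUE)
}

#' Between-group spread and its permutation null
#'
#' The spread statistic is the standard deviation of the group means of
#' a per-locus value (typically central signal means). The null
#' distribution is obtained by permuting group labels; a genuine planted
#' ordering gives an observed spread far above the null, while a
#' randomised grouping falls within it.
#'
#' @param values named numeric vector of per-locus statistics.
#' @param groups named character vector mapping locus ids to groups.
#' @param n_perm number of label permutations, default 200.
#' @param seed mandatory RNG seed.
#' @return list with `observed`, `null` (vector of permuted spreads),
#'   `null_mean`, `null_sd`.
#' @export
randomization_spread <- function(values, groups, n_perm = 200, seed) {
  if (missing(seed)) stop("a seed is required for randomization")
  groups <- as.character(groups[names(values)])
  keep <- !is.na(groups) & !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  spread <- function(g) stats::sd(tapply(values, g, mean))
  observed <- spread(groups)
  null <- .with_seed(seed, vapply(seq_len(n_perm), function(i)
    spread(sample(groups)), 0))
  list(observed = observed, null = null,
       null_mean = mean(null), null_sd = stats::sd(null))
}
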