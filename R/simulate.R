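#' Configuration for the synthetic chromatin dataset
#'
#' Bundles the genome geometry, locus-class counts, nucleosome grid,
#' sequencing depth, and the planted effects: per-nucleosome H4K16ac
#' depletion (log2 units, strongest at the -1/+1 nucleosomes), a
#' per-origin responsiveness score s in [0, 1] drawn from a Beta
#' distribution, Sir2/Sir3 occupancy gains proportional to s, MCM peak
#' amplitudes, and the Bernoulli rescue probability in the cdc6-4
#' sir2del genotype.
#'
#' Locus-class counts default to 259 origins, 179 non-origin ORC-site
#' loci and 239 intergenic controls — the group sizes of the chromosomal
#' analyses this generator emulates.
#'
#' @param seed RNG seed (mandatory; all draws derive from it).
#' @param n_chrom,chrom_size genome shape; defaults 8 x 250 kb.
#' @param n_origin,n_nonorigin,n_control locus-class counts.
#' @param n_het_loci heterochromatic (HM-like) origins placed inside
#'   heterochromatin blocks, default 4.
#' @param het_block_bp width of the one internal heterochromatin block
#'   per chromosome, default 10000; 0 disables blocks.
#' @param telomere_bp loci are placed clear of this distance from
#'   chromosome ends, default 15000.
#' @param nucleosome_spacing dyad-to-dyad spacing of the background
#'   nucleosome grid, default 165 bp.
#' @param ndr_halfwidth half-width of the nucleosome-depleted region at
#'   each ORC site, default 80 bp.
#' @param read_depth target mean per-nucleotide coverage per sample,
#'   default 20; 0 gives empty read sets.
#' @param read_length read length in bp, default 50.
#' @param base_acetyl baseline acetylation rate a0 (arbitrary units),
#'   default 1.
#' @param chip_scale global ChIP-vs-input scale factor (exercises the
#'   baseline normalisation), default 0.8.
#' @param background_rate non-origin coverage rate, default 1.
#' @param depletion_effects named log2 depletion per nucleosome position
#'   (scaled per origin by s); default -0.2/-0.4/-0.6 outward-in.
#' @param sir_gain named multiplicative Sir2/Sir3 occupancy gain per
#'   position (scaled by s), strongest at -1/+1.
#' @param het_sir_gain Sir enrichment factor inside heterochromatin
#'   blocks, default 8.
#' @param mcm_amplitude_meanlog,mcm_amplitude_sdlog lognormal parameters
#'   of per-origin MCM peak amplitude (units of background), defaults
#'   log(10) and 0.3.
#' @param mcm_width Gaussian sd of the MCM peak shape in bp, default 200.
#' @param rescue_fraction Bernoulli probability that an origin is
#'   rescued in cdc6-4 sir2del cells, default 0.83.
#' @param responsiveness_beta shape parameters of the Beta distribution
#'   of s, default c(2, 2).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chrom = 8L, chrom_size = 250000L,
                       n_origin = 259L, n_nonorigin = 179L,
                       n_control = 239L, n_het_loci = 4L,
                       het_block_bp = 10000L, telomere_bp = 15000L,
                       nucleosome_spacing = 165L, ndr_halfwidth = 80L,
                       read_depth = 20, read_length = 50L,
                       base_acetyl = 1, chip_scale = 0.8,
                       background_rate = 1,
                       depletion_effects = c(`-3` = -0.2, `-2` = -0.4,
                                             `-1` = -0.6, `+1` = -0.6,
                                             `+2` = -0.4, `+3` = -0.2),
                       sir_gain = c(`-3` = 0.5, `-2` = 1, `-1` = 2,
                                    `+1` = 2, `+2` = 1, `+3` = 0.5),
                       het_sir_gain = 8,
                       mcm_amplitude_meanlog = log(10),
                       mcm_amplitude_sdlog = 0.3,
                       mcm_width = 200,
                       rescue_fraction = 0.83,
                       responsiveness_beta = c(2, 2)) {
  if (missing(seed)) stop("sim_config requires a seed")
  cfg <- as.list(environment())
  if (rescue_fraction < 0 || rescue_fraction > 1)
    stop("rescue_fraction must lie in [0, 1]")
  if (read_depth < 0) stop("read_depth must be non-negative")
  if (!identical(sort(names(depletion_effects)), sort(NUC_POSITIONS)) ||
      !identical(sort(names(sir_gain)), sort(NUC_POSITIONS)))
    stop("depletion_effects and sir_gain must be named by nucleosome position")
  ## deterministic slot placement: verify the genome can hold the loci
  slots <- .placement_slots(cfg)
  n_tot <- n_origin + n_nonorigin + n_control
  if (nrow(slots) < n_tot)
    stop("config error: ", n_tot, " loci do not fit in ", n_chrom, " x ",
         chrom_size, " bp (", nrow(slots), " placement slots)")
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale simulation preset
#'
#' A small configuration (2 chromosomes x 300 kb, 60/40/50 loci) for
#' examples and fast tests; all planted effects keep their defaults.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
desk_sim_config <- function(seed, ...) {
  args <- list(seed = seed, n_chrom = 2L, chrom_size = 300000L,
               n_origin = 60L, n_nonorigin = 40L, n_control = 50L,
               n_het_loci = 2L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

## fixed heterochromatin block per chromosome (internal, HM/rDNA-like)
.het_blocks <- function(cfg, chrom_names) {
  if (cfg$het_block_bp <= 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  start <- round(0.45 * cfg$chrom_size)
  data.frame(chrom = chrom_names, start = start,
             end = start + cfg$het_block_bp)
}

## candidate ORC/control centre positions on a 1.5 kb grid, clear of
## telomeres and heterochromatin blocks
.placement_slots <- function(cfg) {
  chrom_names <- paste0("chr", as.character(utils::as.roman(seq_len(cfg$n_chrom))))
  het <- .het_blocks(cfg, chrom_names)
  margin <- cfg$telomere_bp + 700
  out <- list()
  for (cn in chrom_names) {
    pos <- seq.int(margin, cfg$chrom_size - margin, by = 1500L)
    hb <- het[het$chrom == cn, , drop = FALSE]
    for (j in seq_len(nrow(hb)))
      pos <- pos[pos < hb$start[j] - 800 | pos > hb$end[j] + 800]
    if (length(pos))
      out[[cn]] <- data.frame(chrom = cn, pos = pos)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## genomic dyad positions of the six flanking nucleosomes of one locus,
## consistent with the oriented-fragment offset convention
.planted_dyads <- function(orc, strand, cfg) {
  off <- cfg$ndr_halfwidth + 73 + (0:2) * cfg$nucleosome_spacing
  sgn <- if (strand == "+") 1 else -1
  stats::setNames(c(orc - sgn * rev(off), orc + sgn * off),
                  c("-3", "-2", "-1", "+1", "+2", "+3"))
}

#' Simulate the full origin-chromatin dataset
#'
#' Generates a toy yeast-like genome: chromosomes with one internal
#' heterochromatin block each, classified loci placed on a jittered grid
#' clear of telomeres and heterochromatin, a regular nucleosome grid
#' interrupted by an NDR (with three positioned nucleosomes on each
#' side) at every ORC site, and Poisson read sets per sample whose
#' expected per-nucleotide rate is background plus the planted
#' locus/mark/genotype effects:
#'
#' * H4K16ac ChIP at origin nucleosome p: `a0 * 2^(delta_p * s)` in
#'   SIR2 genotypes, flat `a0` in sir2del; non-origin ORC loci and
#'   controls are flat everywhere.
#' * Sir2/Sir3 ChIP at origin nucleosome p: `background * (1 +
#'   gain_p * s)`, plus a strong flat gain inside heterochromatin
#'   blocks.
#' * MCM: a Gaussian peak of amplitude m at each origin in wild type
#'   and sir2del, background only in cdc6-4, and `m * s * 1(rescued)`
#'   in cdc6-4 sir2del with `rescued ~ Bernoulli(rescue_fraction)`.
#'
#' All draws are reproducible from `config$seed`; identical configs give
#' identical outputs.
#'
#' @param config a [sim_config()].
#' @param samples character vector of sample labels to generate; any of
#'   `mcm_wt`, `mcm_sir2d`, `mcm_cdc64`, `mcm_cdc64_sir2d`,
#'   `h4k16_sir2_chip`, `h4k16_sir2_input`, `h4k16_sir2d_chip`,
#'   `h4k16_sir2d_input`, `sir3_chip`, `sir3_input`, `sir2_chip`,
#'   `sir2_input`. Defaults to the first ten.
#' @return list of class `sim_dataset` with `layout` (genome layout with
#'   het blocks), `loci`, `dyads` (chrom/dyad table), `reads` (named
#'   list of read tables), `truth` (per-locus ground truth: class, s,
#'   rescued flag, MCM amplitude, and matrices `delta` / `sir_gain` of
#'   the planted per-position log2 depletion and Sir gain), and the
#'   `config`.
#' @export
simulate_dataset <- function(config,
                             samples = c("mcm_wt", "mcm_sir2d", "mcm_cdc64",
                                         "mcm_cdc64_sir2d",
                                         "h4k16_sir2_chip", "h4k16_sir2_input",
                                         "h4k16_sir2d_chip",
                                         "h4k16_sir2d_input",
                                         "sir3_chip", "sir3_input")) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_dataset_impl(config, samples))
}

.simulate_dataset_impl <- function(cfg, samples) {
  chrom_names <- paste0("chr",
                        as.character(utils::as.roman(seq_len(cfg$n_chrom))))
  sizes <- stats::setNames(rep(cfg$chrom_size, cfg$n_chrom), chrom_names)
  het <- .het_blocks(cfg, chrom_names)
  layout <- genome_layout(sizes, het)

  ## --- place loci -----------------------------------------------------
  slots <- .placement_slots(cfg)
  n_tot <- cfg$n_origin + cfg$n_nonorigin + cfg$n_control
  pick <- sort(sample.int(nrow(slots), n_tot))
  centre <- slots$pos[pick] + sample(-100:100, n_tot, replace = TRUE)
  cls <- sample(rep(c("origin", "nonorigin_orc", "intergenic_control"),
                    times = c(cfg$n_origin, cfg$n_nonorigin, cfg$n_control)))
  strand <- sample(c("+", "-"), n_tot, replace = TRUE)
  prefix <- c(origin = "ori", nonorigin_orc = "norc",
              intergenic_control = "ctrl")[cls]
  idx <- stats::ave(seq_len(n_tot), cls, FUN = seq_along)
  loci <- data.frame(
    id = sprintf("%s_%03d", prefix, idx),
    chrom = slots$chrom[pick],
    start = centre - 600, end = centre + 601,
    locus_class = cls,
    orc_start = ifelse(cls == "intergenic_control", NA_real_, centre),
    t_rich_strand = ifelse(cls == "intergenic_control", NA_character_,
                           strand),
    stringsAsFactors = FALSE)
  ## heterochromatic (HM-like) origins inside the blocks
  if (cfg$n_het_loci > 0 && nrow(het) > 0) {
    hrows <- list()
    k <- 0L
    for (j in seq_len(nrow(het))) {
      c0 <- het$start[j] + 2000
      while (k < cfg$n_het_loci && c0 + 700 < het$end[j]) {
        k <- k + 1L
        hrows[[k]] <- data.frame(
          id = sprintf("het_%03d", k), chrom = het$chrom[j],
          start = c0 - 600, end = c0 + 601,
          locus_class = "heterochromatic", orc_start = c0,
          t_rich_strand = sample(c("+", "-"), 1),
          stringsAsFactors = FALSE)
        c0 <- c0 + 1500
      }
      if (k >= cfg$n_het_loci) break
    }
    loci <- rbind(loci, do.call(rbind, hrows))
  }
  validate_loci(loci, layout)

  ## --- ground truth ---------------------------------------------------
  n <- nrow(loci)
  is_orc <- !is.na(loci$orc_start)
  s_o <- rep(NA_real_, n)
  s_o[loci$locus_class == "origin"] <-
    stats::rbeta(cfg$n_origin, cfg$responsiveness_beta[1],
                 cfg$responsiveness_beta[2])
  s_o[loci$locus_class == "heterochromatic"] <- 1
  rescued <- rep(NA, n)
  rescued[loci$locus_class == "origin"] <-
    stats::rbinom(cfg$n_origin, 1, cfg$rescue_fraction) == 1
  rescued[loci$locus_class == "heterochromatic"] <- TRUE
  m_o <- rep(NA_real_, n)
  n_amp <- sum(loci$locus_class %in% c("origin", "heterochromatic"))
  m_o[loci$locus_class %in% c("origin", "heterochromatic")] <-
    stats::rlnorm(n_amp, cfg$mcm_amplitude_meanlog, cfg$mcm_amplitude_sdlog)
  delta <- matrix(0, n, 6, dimnames = list(loci$id, NUC_POSITIONS))
  gain <- matrix(0, n, 6, dimnames = list(loci$id, NUC_POSITIONS))
  ori <- which(loci$locus_class == "origin")
  for (p in NUC_POSITIONS) {
    delta[ori, p] <- cfg$depletion_effects[[p]] * s_o[ori]
    gain[ori, p] <- cfg$sir_gain[[p]] * s_o[ori]
  }
  truth <- data.frame(id = loci$id, class = loci$locus_class,
                      chrom = loci$chrom, orc_start = loci$orc_start,
                      t_rich_strand = loci$t_rich_strand,
                      s_o = s_o, rescued = rescued, mcm_amplitude = m_o,
                      stringsAsFactors = FALSE)
  attr(truth, "delta") <- delta
  attr(truth, "sir_gain") <- gain

  ## --- nucleosome dyads ----------------------------------------------
  planted <- lapply(which(is_orc), function(i)
    .planted_dyads(loci$orc_start[i], loci$t_rich_strand[i], cfg))
  names(planted) <- loci$id[is_orc]
  dy_list <- lapply(chrom_names, function(cn) {
    d <- seq.int(100, sizes[[cn]] - 100, by = cfg$nucleosome_spacing)
    orcs <- loci$orc_start[is_orc & loci$chrom == cn]
    for (o in orcs) d <- d[abs(d - o) > 600 + 74]
    local_d <- unlist(planted[loci$id[is_orc & loci$chrom == cn]],
                      use.names = FALSE)
    sort(c(d, local_d))
  })
  dyads <- data.frame(chrom = rep(chrom_names, lengths(dy_list)),
                      dyad = unlist(dy_list, use.names = FALSE))

  ## --- per-sample rates and reads ------------------------------------
  reads <- list()
  for (smp in samples) {
    rates <- .sample_rates(smp, cfg, sizes, loci, truth, planted)
    reads[[smp]] <- .draw_reads(rates, cfg)
  }

  structure(list(layout = layout, loci = loci, dyads = dyads,
                 reads = reads, truth = truth, config = cfg),
            class = "sim_dataset")
}

## multiply rate over nucleosome windows of one locus
.apply_windows <- function(v, dyads_by_pos, factors) {
  for (p in names(dyads_by_pos)) {
    d <- dyads_by_pos[[p]]
    lo <- max(0, d - 73); hi <- min(length(v), d + 74)
    if (hi > lo) v[(lo + 1):hi] <- v[(lo + 1):hi] * factors[[p]]
    }
  v
}

## expected per-nucleotide rate vectors for one sample
.sample_rates <- function(sample, cfg, sizes, loci, truth, planted) {
  delta <- attr(truth, "delta"); gain <- attr(truth, "sir_gain")
  het <- .het_blocks(cfg, names(sizes))
  rates <- lapply(names(sizes), function(cn) {
    size <- sizes[[cn]]
    if (startsWith(sample, "mcm_")) {
      v <- rep(cfg$background_rate, size)
      geno <- sub("^mcm_", "", sample)
      sel <- which(loci$chrom == cn &
                     loci$locus_class %in% c("origin", "heterochromatic"))
      for (i in sel) {
        coef <- switch(geno,
                       wt = 1, sir2d = 1, cdc64 = 0,
                       cdc64_sir2d = as.numeric(truth$rescued[i]) *
                         truth$s_o[i],
                       stop("unknown MCM genotype '", geno, "'"))
        if (coef <= 0) next
        amp <- truth$mcm_amplitude[i] * cfg$background_rate * coef
        orc <- loci$orc_start[i]
        lo <- max(0, orc - 600); hi <- min(size, orc + 601)
        x <- (lo + 1):hi
        v[x] <- v[x] + amp * exp(-((x - 1) - orc)^2 / (2 * cfg$mcm_width^2))
      }
      v
    } else if (startsWith(sample, "h4k16_")) {
      chip <- endsWith(sample, "_chip")
      v <- rep(cfg$base_acetyl * if (chip) cfg$chip_scale else 1, size)
      if (chip && grepl("_sir2_", sample)) {   # SIR2 genotype: depletion on
        sel <- which(loci$chrom == cn & loci$locus_class == "origin")
        for (i in sel)
          v <- .apply_windows(v, planted[[loci$id[i]]],
                              2^delta[loci$id[i], ])
      }
      v
    } else if (startsWith(sample, "sir3") || startsWith(sample, "sir2")) {
      chip <- endsWith(sample, "_chip")
      v <- rep(cfg$background_rate * if (chip) cfg$chip_scale else 1, size)
      if (chip) {
        sel <- which(loci$chrom == cn & loci$locus_class == "origin")
        for (i in sel)
          v <- .apply_windows(v, planted[[loci$id[i]]],
                              1 + gain[loci$id[i], ])
        hb <- het[het$chrom == cn, , drop = FALSE]
        for (j in seq_len(nrow(hb)))
          v[(hb$start[j] + 1):hb$end[j]] <-
            v[(hb$start[j] + 1):hb$end[j]] * cfg$het_sir_gain
      }
      v
    } else stop("unknown sample label '", sample, "'")
  })
  names(rates) <- names(sizes)
  rates
}

## Poisson read starts proportional to the local rate, fixed read length
.draw_reads <- function(rates, cfg) {
  L <- cfg$read_length
  mean_rate <- mean(unlist(lapply(rates, mean), use.names = FALSE))
  scale <- if (mean_rate > 0) cfg$read_depth / mean_rate else 0
  out <- list()
  for (cn in names(rates)) {
    v <- rates[[cn]]
    n_start <- length(v) - L + 1L
    if (n_start < 1 || scale == 0) next
    lambda <- v[seq_len(n_start)] * scale / L
    counts <- stats::rpois(n_start, lambda)
    nz <- which(counts > 0)
    if (!length(nz)) next
    starts <- rep(nz - 1L, counts[nz])
    out[[cn]] <- data.frame(chrom = cn, start = starts, end = starts + L)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-nucleotide coverage for one simulated sample
#'
#' Convenience wrapper around [coverage_from_reads()].
#'
#' @param sim a `sim_dataset`.
#' @param sample sample label present in `sim$reads`.
#' @return per-nucleotide `coverage_track`.
#' @export
sim_coverage <- function(sim, sample) {
  if (!(sample %in% names(sim$reads)))
    stop("sample '", sample, "' was not generated")
  coverage_from_reads(sim$reads[[sample]], sim$layout, sample_label = sample)
}
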