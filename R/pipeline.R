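#' Assemble a run configuration
#'
#' Collects the simulation block and every stage parameter, with the
#' seed plumbing for all stochastic stages (simulation = `seed`,
#' randomisation control = `seed + 1`, qPCR = `seed + 2`). Validation
#' happens before any compute: a missing seed fails immediately.
#'
#' @param seed master seed (mandatory).
#' @param sim a [sim_config()]; defaults to [desk_sim_config()] under
#'   `seed`.
#' @param bin MCM bin width in bp, default 25.
#' @param top_n peaks retained per genotype, default 400.
#' @param flank fragment half-width, default 600.
#' @param pseudocount for log2 enrichment, default 0.5.
#' @param telomere_bp telomere exclusion distance, default 15000.
#' @param central_window offsets summarised in the randomisation
#'   control, default c(-200, 200).
#' @param n_perm label permutations for the null spread, default 200.
#' @param qpcr list with `samples` (named list: per strain, named vector
#'   of true copy numbers), `noise_sd`, `replicates`.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(seed, sim = NULL, bin = 25, top_n = 400,
                            flank = 600, pseudocount = 0.5,
                            telomere_bp = 15000,
                            central_window = c(-200, 200), n_perm = 200,
                            qpcr = list(
                              samples = list(
                                wt = c(NTS2 = 150, X35S = 150, ERV46 = 1),
                                cdc64_sir2d = c(NTS2 = 110, X35S = 110,
                                                ERV46 = 1)),
                              noise_sd = 0.2, replicates = 3)) {
  if (missing(seed) || !is.numeric(seed))
    stop("pipeline_config requires an integer seed")
  if (is.null(sim)) sim <- desk_sim_config(seed = seed)
  cfg <- list(seed = as.integer(seed), sim = sim, bin = bin, top_n = top_n,
              flank = flank, pseudocount = pseudocount,
              telomere_bp = telomere_bp, central_window = central_window,
              n_perm = n_perm, qpcr = qpcr)
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full origin-chromatin pipeline
#'
#' Simulate-then-analyse driver producing the figure-level outputs as
#' TSV tables in `outdir`: per-genotype MCM peak tables (TSV and BED),
#' origin-overlap and rescue statistics, the peak/origin saturation
#' table, the responsiveness table with quintiles, nucleosome group
#' profiles with Student's t p-values (per genotype, grouped by locus
#' class and by responsiveness group), per-nucleotide Sir3 meta-profiles
#' under both baseline modes, the randomisation-control summary, qPCR
#' copy-number estimates, and a manifest recording the configuration and
#' the MD5 of every table. Reruns with the same configuration give
#' byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @return the report bundle, invisibly: a list with all tables plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) stop("config lacks a seed")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  sim <- .stage("simulate", simulate_dataset(config$sim))
  loci <- .stage("filter", apply_heterochromatin_filter(
    sim$loci, sim$layout, telomere_bp = config$telomere_bp))
  origins <- loci[loci$locus_class == "origin", ]

  ## --- MCM stage ------------------------------------------------------
  genos <- c("wt", "sir2d", "cdc64", "cdc64_sir2d")
  mcm <- .stage("mcm_tracks", {
    tr <- lapply(genos, function(g)
      bin_track(sim_coverage(sim, paste0("mcm_", g)), bin = config$bin))
    names(tr) <- genos
    ref <- tr$cdc64
    lapply(tr, function(t)
      if (identical(t, ref)) t else scale_to_reference(t, ref))
  })
  peaks <- .stage("peaks", lapply(mcm, call_top_peaks, n = config$top_n))
  idsets <- lapply(peaks, origins_identified, loci = origins)
  overlap <- .stage("overlap",
                    set_overlap_stats(idsets$wt, idsets$sir2d))
  rescue <- .stage("rescue",
                   rescue_fraction(idsets$cdc64_sir2d, idsets$wt,
                                   idsets$sir2d))
  saturation <- .stage("saturation",
                       peak_origin_saturation(peaks$wt, origins))
  windows <- .stage("windows",
                    define_origin_windows(peaks$wt, origins, sim$layout))
  signals <- .stage("signals", origin_signals(mcm, windows))
  resp <- .stage("responsiveness", responsiveness_table(signals))
  for (g in genos) {
    files <- c(files, .write_tsv(peaks[[g]], outdir, paste0("peaks_", g)))
    files <- c(files, write_peaks_bed(
      peaks[[g]], file.path(outdir, paste0("peaks_", g, ".bed"))))
  }
  files <- c(files,
             .write_tsv(as.data.frame(overlap), outdir, "overlap_stats"),
             .write_tsv(as.data.frame(rescue), outdir, "rescue_stats"),
             .write_tsv(saturation, outdir, "peak_origin_saturation"),
             .write_tsv(resp, outdir, "responsiveness"))

  ## --- nucleosome profiles (H4K16ac, both genotypes) ------------------
  resp_groups <- stats::setNames(resp$group, resp$id)
  nuc_tables <- list()
  for (g in c("sir2", "sir2d")) {
    prof <- .stage(paste0("nucprofile_", g), build_nuc_profile(
      loci, sim$dyads,
      mark = sim_coverage(sim, paste0("h4k16_", g, "_chip")),
      denom = sim_coverage(sim, paste0("h4k16_", g, "_input")),
      layout = sim$layout, flank = config$flank))
    by_class <- do.call(rbind, lapply(
      c(origin = "origin", nonorigin = "nonorigin_orc"), function(cl)
        group_profile(prof$normalized,
                      prof$loci$id[prof$loci$locus_class == cl],
                      prof$control_pool, group_label = cl)))
    by_resp <- do.call(rbind, lapply(c("low", "medium", "high"), function(gr)
      group_profile(prof$normalized, names(resp_groups)[resp_groups == gr],
                    prof$control_pool, group_label = gr)))
    box <- boxplot_summary(
      prof$normalized,
      stats::setNames(prof$loci$locus_class, prof$loci$id))
    nuc_tables[[g]] <- list(profile = prof, by_class = by_class,
                            by_resp = by_resp, box = box)
    files <- c(files,
               .write_tsv(by_class, outdir, paste0("nuc_group_class_", g)),
               .write_tsv(by_resp, outdir, paste0("nuc_group_resp_", g)),
               .write_tsv(box, outdir, paste0("nuc_box_", g)),
               .write_tsv(cbind(id = rownames(prof$normalized),
                                as.data.frame(prof$normalized)),
                          outdir, paste0("nuc_matrix_", g)))
  }

  ## --- per-nucleotide Sir3 meta-profiles ------------------------------
  sir3_chip <- sim_coverage(sim, "sir3_chip")
  sir3_input <- sim_coverage(sim, "sir3_input")
  frags <- orient_fragments(loci, sim$layout, flank = config$flank)
  class_groups <- stats::setNames(loci$locus_class, loci$id)[names(frags)]
  meta_tables <- list()
  for (mode in c("excluded", "genomewide")) {
    mask <- if (mode == "excluded") sim$layout$het_intervals else NULL
    signal <- .stage(paste0("normalize_", mode), log2_enrichment(
      depth_breadth_normalize(sir3_chip, mask, mask_label = mode),
      depth_breadth_normalize(sir3_input, mask, mask_label = mode),
      pseudocount = config$pseudocount))
    prof_class <- grouped_meta_profiles(signal, frags, class_groups)
    prof_resp <- grouped_meta_profiles(signal, frags, resp_groups)
    meta_tables[[mode]] <- list(by_class = prof_class, by_resp = prof_resp,
                                signal = signal)
    files <- c(files,
               .write_tsv(do.call(rbind, prof_class), outdir,
                          paste0("metaprofile_class_", mode)),
               .write_tsv(do.call(rbind, prof_resp), outdir,
                          paste0("metaprofile_resp_", mode)))
  }

  ## --- randomisation control ------------------------------------------
  rand <- .stage("randomization", {
    signal <- meta_tables$excluded$signal
    grouped_ids <- names(resp_groups)[resp_groups %in%
                                        c("low", "medium", "high")]
    frs <- frags[names(frags) %in% grouped_ids]
    central <- central_locus_means(signal, frs, config$central_window)
    gr <- resp_groups[names(central)]
    sizes <- table(gr)
    rnd <- randomized_groups(names(central), k = length(sizes),
                             seed = config$seed + 1L,
                             sizes = as.integer(sizes),
                             labels = names(sizes))
    planted <- randomization_spread(central, gr, n_perm = config$n_perm,
                                    seed = config$seed + 1L)
    randomized <- randomization_spread(central, rnd,
                                       n_perm = config$n_perm,
                                       seed = config$seed + 1L)
    data.frame(grouping = c("responsiveness", "randomized"),
               observed_spread = c(planted$observed, randomized$observed),
               null_mean = c(planted$null_mean, randomized$null_mean),
               null_sd = c(planted$null_sd, randomized$null_sd))
  })
  files <- c(files, .write_tsv(rand, outdir, "randomization_control"))

  ## --- qPCR ------------------------------------------------------------
  qpcr <- .stage("qpcr", {
    wells <- do.call(rbind, lapply(seq_along(config$qpcr$samples), function(i)
      simulate_qpcr(config$qpcr$samples[[i]],
                    noise_sd = config$qpcr$noise_sd,
                    replicates = config$qpcr$replicates,
                    seed = config$seed + 2L + i,
                    sample_id = names(config$qpcr$samples)[i])))
    replicate_summary(wells)
  })
  files <- c(files, .write_tsv(qpcr, outdir, "qpcr_estimates"))

  ## --- manifest --------------------------------------------------------
  manifest <- list(
    package = "orichrom",
    version = as.character(utils::packageVersion("orichrom")),
    seed = config$seed,
    config = .config_snapshot(config),
    files = as.list(stats::setNames(
      unname(tools::md5sum(sort(files))), basename(sort(files)))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(sim = sim, loci = loci, peaks = peaks, overlap = overlap,
                 rescue = rescue, saturation = saturation,
                 responsiveness = resp, nucleosome = nuc_tables,
                 metaprofiles = meta_tables, randomization = rand,
                 qpcr = qpcr, manifest = manifest))
}

## plain-list config snapshot for the manifest
.config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$sim <- unclass(snap$sim)
  snap$qpcr$samples <- lapply(snap$qpcr$samples, as.list)
  snap$sim$depletion_effects <- as.list(snap$sim$depletion_effects)
  snap$sim$sir_gain <- as.list(snap$sim$sir_gain)
  snap
}
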