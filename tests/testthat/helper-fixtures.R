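# small deterministic fixtures shared across tests

toy_layout <- function(sizes = c(chrA = 1000), het = NULL)
  genome_layout(sizes, het)

toy_track <- function(values, resolution = 1, label = "toy") {
  if (!is.list(values)) values <- list(chrA = values)
  coverage_track(values, resolution = resolution, sample_label = label)
}

toy_locus <- function(id = "L1", chrom = "chrA", start = 0, end = 1000,
                      class = "origin", orc = 500, strand = "+") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             locus_class = class,
             orc_start = if (class == "intergenic_control") NA_real_ else orc,
             t_rich_strand = if (class == "intergenic_control")
               NA_character_ else strand,
             stringsAsFactors = FALSE)
}

# signed per-nucleotide signal (e.g. log2 enrichment), bypassing the
# non-negativity check that applies to raw coverage
toy_signal <- function(values) {
  if (!is.list(values)) values <- list(chrA = values)
  structure(list(values = values, resolution = 1, sample_label = "signal",
                 baseline_mask_label = "none"),
            class = c("normalized_track", "coverage_track"))
}

# brute-force per-position read membership count
brute_coverage <- function(reads, size) {
  vapply(seq_len(size) - 1L, function(p)
    sum(reads$start <= p & reads$end > p), 0L)
}
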