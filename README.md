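# orichrom

Origin-centric chromatin profiling from ChIP-seq in budding yeast.

In *Saccharomyces cerevisiae*, replication origins are licensed in G1 by
loading of the MCM helicase at ORC-bound sites. The SIR2 histone
deacetylase restrains this step: deleting *SIR2* rescues MCM loading in
loading-defective *cdc6-4* cells, and the chromatin around euchromatic
origins shows a matching signature — depletion of H4K16 acetylation on
the nucleosomes flanking the origin, and detectable Sir2/Sir3 binding
there, both scaling with how strongly each origin responds to loss of
*SIR2*. `orichrom` implements the analyses needed to quantify this
picture from coverage-level ChIP-seq data, for researchers studying
replication origin licensing and chromatin state:

* **MCM peak statistics** — 25-bp binning, top-*N* peak ranking with
  origin-overlap saturation per 100-peak block, origin-set overlap and
  rescue percentages across genotypes (*CDC6 SIR2*, *CDC6 sir2Δ*,
  *cdc6-4*, *cdc6-4 sir2Δ*), and per-origin signal areas in windows
  defined once in wild type and reused verbatim.
* **SIR2-responsiveness** — per origin, the ratio
  `r = signal(cdc6-4 sir2Δ) / signal(sir2Δ)` (near 1 = fully rescued),
  ranked and split into quintiles; the low/medium/high groups are
  quintiles 1/3/5.
* **Nucleosome-resolved mark profiles** — 1201-bp fragments oriented
  with the T-rich strand of the ORC site 5'→3' (first ORC-site
  nucleotide = position 0), the six proximal nucleosomes assigned
  nearest-first on each side, mark/input ratios per 147-bp core
  particle, log2-normalised to the mean level of nucleosomes from
  intergenic control loci, and per-group summaries with pooled-variance
  Student's t-tests against the control pool.
* **Per-nucleotide meta-profiles** — coverage normalised to
  depth/breadth, `v_i = c_i / (D / B)` with `D` the total counted
  signal and `B` the number of covered positions (optionally excluding
  SIR-heterochromatic domains from the baseline), log2 ChIP/input
  enrichment, per-offset means over the oriented fragments, grouped by
  locus class or responsiveness, with a label-randomisation control.
* **qPCR copy number** — `2^-ΔCt` against a single-copy reference
  (*RIM15*), summarised per biological replicate.
* **Synthetic data** — a generator that plants all of the above effects
  (per-nucleosome H4K16ac depletion `δ_p · s`, Sir3 gain `∝ s`, MCM
  rescue with probability `f`) with known per-locus ground truth, so
  every stage is testable by parameter recovery.

## Worked example

Simulate a desk-scale dataset (2 × 300 kb, 60 origins / 40 non-origin
ORC-site loci / 50 intergenic controls, 20× coverage), then recover the
planted H4K16ac depletion around origins in SIR2 cells:

```r
library(orichrom)

cfg  <- desk_sim_config(seed = 7)
sim  <- simulate_dataset(cfg)
loci <- apply_heterochromatin_filter(sim$loci, sim$layout)

prof <- build_nuc_profile(loci, sim$dyads,
                          mark   = sim_coverage(sim, "h4k16_sir2_chip"),
                          denom  = sim_coverage(sim, "h4k16_sir2_input"),
                          layout = sim$layout)
origin_ids <- loci$id[loci$locus_class == "origin"]
group_profile(prof$normalized, origin_ids, prof$control_pool, "origin")
#>   position  n    mean     se     t        p
#> 1       -3 60 -0.0775 0.0327 -1.55 1.21e-01
#> 2       -2 60 -0.1359 0.0339 -3.16 1.70e-03
#> 3       -1 60 -0.2904 0.0266 -7.71 1.24e-13
#> 4       +1 60 -0.2159 0.0373 -5.29 2.17e-07
#> 5       +2 60 -0.2344 0.0332 -5.92 7.68e-09
#> 6       +3 60 -0.1050 0.0331 -2.31 2.12e-02
```

The origin-flanking nucleosomes are depleted for the mark (negative
log2 means, strongest at −1/+1 where the generator plants −0.6 log2
units scaled by each origin's responsiveness, here averaging ≈ −0.3),
and the t-tests against the 50-control-locus nucleosome pool are
strongly significant at the inner positions — the synthetic analogue of
the origin-specific H4K16ac depletion signature.

Copy-number estimation from simulated qPCR wells:

```r
wells <- simulate_qpcr(c(NTS2 = 150, ERV46 = 1), noise_sd = 0.2,
                       replicates = 3, seed = 8)
replicate_summary(wells)
#>   sample_id target n mean_enrichment      se
#> 1   strain1   NTS2 3           147.8 13.3288
#> 2   strain1  ERV46 3             1.2  0.1598
```

A ~150-copy rDNA-like target and a single-copy control are recovered
from three replicates.

The full simulate-then-analyse pipeline, including the MCM rescue
statistics, responsiveness quintiles, Sir3 meta-profiles under both
baseline modes, the randomisation control, and a reproducibility
manifest, runs with:

```r
run_pipeline(pipeline_config(seed = 1), "out/")
```

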