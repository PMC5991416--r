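---
title: "Methods: origin-centric chromatin profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: origin-centric chromatin profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orichrom)
```

# Scope and coordinate conventions

`orichrom` quantifies chromatin state around budding-yeast replication
origins from coverage-level ChIP-seq data: MCM licensing across
genotypes, a per-origin SIR2-responsiveness metric, nucleosome-resolved
histone-mark profiles, per-nucleotide Sir protein meta-profiles, and
2^-dCt qPCR copy-number estimation. Read alignment is out of scope; the
package starts from read-coordinate tables or coverage tracks.

All coordinates are 0-based half-open internally, matching BED on disk;
1-based coordinates appear only in imported/exported interchange formats
that require them. Loci come in four classes: confirmed origins,
non-origin intergenic regions with an ORC-site match (the
sequence-matched negative control for origin-specific chromatin),
intergenic controls with neither (the normalisation baseline), and
heterochromatic loci (HM silencers, rDNA, subtelomeric), which are
excluded from euchromatic analyses together with anything within 15 kb
of a chromosome end. Exclusion is conservative: a locus is removed if
its interval overlaps a heterochromatin block by at least 1 bp or if
either interval edge lies within the telomeric distance. Filtering is
idempotent.

Fragments are oriented by the ORC site: position 0 is the first
nucleotide of the ORC site read along its T-rich strand, and offsets
increase 5'→3' along that strand, so a "−"-strand locus maps offset
`x` to `orc_start − x`. With the default 600-bp flank a fragment covers
1201 positions. Fragments that would cross a chromosome end are dropped
by default to avoid silent edge artifacts; `pad_missing = TRUE` keeps
them with missing values instead.

# Coverage and normalisation

Coverage counts, per nucleotide, the reads whose interval contains that
nucleotide. Binned tracks (25 bp for the MCM analyses) hold bin sums,
with a partial final bin, so total signal is conserved at any bin size.

The per-nucleotide normalisation divides each count by depth/breadth:
`v_i = c_i / (D / B)`, with `D` the summed counts and `B` the number of
covered positions, both over positions outside an optional exclusion
mask. "Depth" is implemented as summed per-nucleotide counts (total
aligned bases) rather than a read count; the two differ only by a
constant at fixed read length, and this choice gives the clean invariant
that the mean of `v_i` over unmasked covered positions is exactly 1.
Masked positions still receive values — they just do not shape `D` and
`B` — so profiles over masked loci remain computable and the only thing
that changes between the heterochromatin-excluded and genome-wide
baseline modes is the normalisation constant. Excluding Sir-bound
heterochromatin from the baseline of a Sir3 ChIP raises the apparent
euchromatic signal, since heterochromatic reads no longer inflate `D`.

Log2 enrichment is `log2((chip_i + q) / (input_i + q))` with a
pseudocount `q = 0.5` in normalised units (where background sits near
1); the pseudocount guards against log of zero and shrinks
low-coverage positions toward 0. Cross-genotype MCM comparisons first
scale every track to the total of the cdc6-4 track (the no-loading
noise floor), which preserves rankings and makes areas comparable.

# MCM peaks, rescue statistics, responsiveness

Peak calling is deliberately simple — a ranking heuristic, not a
statistical caller: smooth each chromosome with a 3-bin centred rolling
mean, take local maxima above the genome-wide median of the smoothed
signal as seeds, merge seeds within 500 bp, score each merged peak by
its summed smoothed signal, and keep the top N (default 400, ties broken
by leftmost coordinate). Rankings are invariant to positive rescaling of
the track. On tracks whose background occupies most of the genome the
seed rule necessarily chains background maxima into long merged spans
(half of all background bins sit above the median); the top-N list is
then noisier than one from a model-based caller, which is a known
limitation of this heuristic rather than a target of the package.

Origin-set statistics follow printed-count conventions: the overlap
percentage between two genotypes' origin sets uses the smaller set as
denominator (330 shared origins out of 338 and 340 → 97.6%), and the
rescue percentage divides the rescued origins found in either
proficient set by the proficient core (their intersection; 272/330 →
82.4%).

Per-origin signal areas use windows defined once in the reference
(wild-type) sample — the union of the origin interval with any
overlapping wild-type peak span, padded by 250 bp — and reused verbatim
in every genotype. SIR2-responsiveness is
`r = signal(cdc6-4 sir2Δ) / signal(sir2Δ)` on these areas; origins are
ranked by `r` (ties by id, so results are independent of input order)
and divided into quintiles whose sizes differ by at most one, quintile
5 = most responsive; low/medium/high are quintiles 1/3/5.

Because the windows contain background as well as peak signal, the raw
ratio of a non-rescued origin sits near `background / (background +
peak)` rather than 0. For estimating the *fraction* of rescued origins,
`estimate_rescued_fraction()` therefore subtracts the cdc6-4 area from
each genotype's area after rescaling it by the ratio of genome-wide
median bin levels (a robust background-level match that is insensitive
to how samples were depth-scaled), and classifies an origin as rescued
when the background-subtracted ratio exceeds a cutoff (default 0.05).
The cutoff plays the role of the threshold separating responsive from
non-responsive origins in the chromosomal ranking; no canonical value
is asserted for it, and it is exposed as a parameter.

# Nucleosome-resolved profiles

Nucleosome windows are the canonical 147-bp core particle, dyad −73 to
+74; callers can supply any dyad atlas as a (chrom, dyad) table. Within
an oriented fragment, dyads are converted to offsets and the three
nearest on each side of the ORC site become positions −1..−3 and
+1..+3, nearest first; unfillable slots stay missing.

The per-nucleosome value is the ratio of summed mark signal to summed
denominator signal over the window. The denominator is the input track
by default; nucleosome occupancy can be supplied instead. The baseline
is the mean over intergenic control loci of the per-locus mean ratio of
six contiguous nucleosomes (the run of six whose centre is closest to
the locus midpoint), and every nucleosome everywhere is normalised to
this single scalar as `log2(ratio / baseline)`. Non-positive ratios
become missing.

Group summaries report n, mean, and standard error per position, with a
two-sided pooled-variance Student's t-test against the control pool.
The control pool is all individual control nucleosome values (not
per-locus means): this maximises degrees of freedom and matches the
variance structure of the per-position group values, which are also
individual nucleosome values. Welch's test is available behind a flag.
Degenerate inputs follow fixed conventions: both samples constant and
equal → t = 0, p = 1; constant but unequal → p = 0, flagged degenerate.
Box-whisker summaries use type-7 (linear-interpolation) quantiles with
whiskers at 1.5 IQR clamped to the data range, so expected values in
tests are exact.

One numerical property of this estimator matters when interpreting
near-zero group means: for ratio-of-counts data,
`E[log2(X/Y)] = log2(E[X]/E[Y]) − O(CV²)`, so every group's normalised
log2 mean — including the controls' — carries a small negative offset
that depends on coverage (about −0.02 at 20× with 147-bp windows). The
offset cancels in comparisons *between* a group and the control pool,
which is why group-vs-control differences, not raw means against zero,
are the meaningful null checks; at high coverage the distinction
disappears.

# Per-nucleotide meta-profiles and the randomisation control

A meta-profile is the per-offset mean of a per-nucleotide signal
(typically depth/breadth-normalised log2 ChIP/input) across oriented
fragments, 1201 offsets at the default flank, missing positions
excluded per offset. Profiles can be grouped by locus class or by
responsiveness group. Ordering claims between groups are quantified on
the central window of offsets −200..+200 (about one nucleosome on each
side of the ORC site).

The negative control randomly repartitions the grouped loci into groups
of the same sizes (seeded; all randomisation in the package requires an
explicit seed, and there is no hidden global RNG state). The spread
statistic is the standard deviation of group means of the per-locus
central signal; its null distribution comes from label permutations
(default 200). A planted ordering yields an observed spread far above
the null; after randomisation the spread falls within about two null
standard deviations of the null mean.

# qPCR copy number

Copy number is `2^-(Ct_target − Ct_reference)` against the single-copy
reference locus, assuming ideal primer efficiency (efficiency
correction is instrument-side and out of scope). The difference is taken
within each biological replicate before averaging, which makes
estimates exactly invariant to per-replicate plate shifts; replicate
summaries report the mean and standard error across replicates, and
strain comparisons use ratios of means.

# The synthetic-data generator

The generator builds a toy yeast-like genome — by default 8 chromosomes
of 250 kb, enough to hold the full locus complement of 259 origins, 179
non-origin ORC-site loci and 239 intergenic controls, the group sizes
of the chromosomal analyses it emulates; a desk preset (2 × 300 kb,
60/40/50) serves examples and fast tests. Each chromosome carries one
internal 10-kb heterochromatin block (an HM/rDNA stand-in) holding a
few heterochromatic origins, so the exclusion logic is exercised. Loci
are placed on a jittered 1.5-kb grid clear of telomeres and
heterochromatin, guaranteeing no overlaps; an infeasible request is a
configuration error.

Nucleosomes form a regular 165-bp grid, interrupted at every ORC site
by a nucleosome-depleted region (half-width 80 bp) flanked by three
positioned nucleosomes per side at `orc ± (80 + 73 + 165·(k−1))`,
consistent with the fragment orientation convention.

Expected per-nucleotide rates are background plus planted effects:

* H4K16ac ChIP at origin nucleosome position `p`: `a0 · 2^(δ_p · s)` in
  SIR2 genotypes and flat `a0` in sir2Δ, with `δ` defaulting to
  −0.2/−0.4/−0.6 log2 units outward-in and `s ~ Beta(2, 2)` the
  per-origin responsiveness (smooth, bounded, symmetric — quintiles stay
  well populated). Non-origin ORC-site loci and controls are flat.
* Sir2/Sir3 ChIP: `background · (1 + g_p · s)` at origin nucleosomes
  (`g` strongest at ∓1), times a strong flat gain (default 8×) inside
  heterochromatin blocks.
* MCM: a Gaussian bump (sd 200 bp) of lognormal amplitude at each
  origin in wild type and sir2Δ; background only in cdc6-4; amplitude
  × `s` × 1(rescued) in cdc6-4 sir2Δ, `rescued ~ Bernoulli(f)` with
  `f = 0.83` by default, matching the observed rescue rate.

Reads are Poisson: per-position start counts with rate proportional to
the local expected coverage (scaled so each sample's genome-wide mean
coverage equals `read_depth`, default 20×), placed as fixed-length
50-bp intervals. Identical configurations (including the seed)
reproduce outputs byte-for-byte, and the per-locus truth (`s`, rescue
flag, planted per-position log2 effects) is returned for recovery
tests.

What the generator does *not* emulate: fragment-size distributions and
paired-end structure, GC and mappability bias, biological
locus-to-locus variance beyond the planted `s`, sequence composition,
and replication timing. Passing recovery tests therefore demonstrates
that the estimators retrieve planted effects of realistic size under
Poisson counting noise at realistic coverage — not that the pipeline is
robust to alignment artifacts or library biases of real data.

# Problem sizes and runtime choices

Unit tests run on toy chromosomes (tens of kb) and the desk-scale
generator; recovery checks use the full 259/179/239 complement on the
2-Mb genome at 20× coverage, which keeps a complete simulate-and-recover
cycle within a couple of minutes on one CPU. The permutation null uses
200 reshuffles, enough to place the observed spread within the null to
the 2-SD resolution the control requires.

# Known limitations

* The top-N peak heuristic degenerates on uniform high backgrounds (see
  above); it reproduces a ranking convention, not a peak model.
* The responsiveness ratio is computed on raw window areas, so its
  absolute value is window-dependent; between-group orderings and the
  background-subtracted rescue classification are the stable readouts.
* The pooled-variance t treats control nucleosome values as
  exchangeable; mild within-locus correlation makes the test slightly
  anticonservative at desk scales.
* 2^-dCt assumes perfect doubling per cycle; systematic
  primer-efficiency error propagates multiplicatively into copy-number
  estimates.
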