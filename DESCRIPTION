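Package: orichrom
Title: Origin-Centric Chromatin Profiling from ChIP-Seq in Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing chromatin state around DNA replication
    origins in Saccharomyces cerevisiae. Implements MCM ChIP-Seq peak
    ranking with origin-overlap calibration and rescue statistics, a
    per-origin SIR2-responsiveness metric with quintile stratification,
    nucleosome-resolved histone-mark profiles around ORC-site-oriented
    fragments normalised to intergenic baselines, per-nucleotide
    depth/breadth-normalised Sir2/Sir3 meta-profiles with
    heterochromatin-excluded baselines and randomisation controls, and
    relative copy-number estimation from qPCR Ct values by the 2^-dCt
    method. A synthetic-data generator plants locus-class-dependent
    coverage effects with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
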