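Package: dsbscape
Title: Break-Anchored Sequencing Signal Quantification for DSB Repair Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification and classification of sequencing signals anchored
    on DNA double-strand break (DSB) sites in sequence-specific nuclease
    systems: CPM-normalized binned coverage from aligned reads, break-centered
    windowed read counts, average profiles and cleavage-ordered heatmap
    matrices, enrichment-ratio site classification (e.g. BLM-high/BLM-low),
    quantile occupancy groups with rank-based comparisons, qPCR delta-Ct assay
    calculators (ChIP percent input, resection ssDNA percent, recleavage,
    relative quantity), and a cancer-cohort tandem-duplication analysis with
    negative-binomial interaction regression. Includes a synthetic-data
    forward model emulating the statistical structure of every input (factor
    pileups around cut sites, Ct tables, donor expression and structural
    variant tables) so the whole pipeline runs and is tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    MASS,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
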