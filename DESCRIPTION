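Package: tailsweep
Title: Selective-Sweep Scans, Retrocopy Detection and Tail-Phenotype
    Association for Multi-Population Resequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Window-based selective-sweep discovery for three-population
    resequencing designs: pairwise fixation indices, lineage-specific branch
    lengths (LSBL), between-population distance d_xy, pooled window
    heterozygosity H_P and its genome-wide standardization ZH_P over sliding
    windows, with top-quantile window extraction.  Companion analyses for a
    swept locus: detection of retro-transposed (intron-less) gene copies by an
    in-package seed-chain-extend aligner with per-junction intron-loss
    classification, repeat-class coverage and enrichment from RepeatMasker
    annotation, and genotype-phenotype association under additive, dominant
    and recessive genetic models with age and sex covariates.  A synthetic
    cohort generator with known ground truth (Balding-Nichols drift, planted
    sweeps, planted retrocopies, simulated repeat annotation and phenotypes)
    supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
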