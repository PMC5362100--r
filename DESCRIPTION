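Package: SNPArrayKit
Title: Design and Evaluation of High-Density SNP Genotyping Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for designing high-density SNP genotyping arrays from
    population re-sequencing data and for evaluating the resulting genotype
    calls. Implements per-call invalidation by depth and genotype quality,
    site-level minor-allele-frequency, missing-rate and indel-proximity
    filters, functional effect classification against gene models with
    priority levels, two-pass sliding-window marker selection with
    must-include seeding and capacity control, probe template extraction,
    post-genotyping sample and marker QC (cluster categories, conversion and
    spacing summaries), array-versus-sequencing genotype concordance, and
    Mendelian-consistency error accounting in full-sib families. A seeded
    synthetic-data generator produces genomes, gene models, population VCFs,
    array call matrices and families with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
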