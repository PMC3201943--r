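Package: microXY
Title: Sex-Chromosome Differentiation Scans from Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies X/Y sex-chromosome differentiation from codominant
    multi-allelic marker genotypes. Reads Genepop-format genotype tables with
    separate sex labels and marker maps, computes per-locus and per-sex allele
    counts, observed and unbiased expected heterozygosity, Weir-Cockerham
    F_IS and between-sex F_ST with seeded permutation tests, genotypic
    linkage disequilibrium, allele-dosage trend tests for sex association,
    and homozygote-excess null-allele estimators. Loci are classified as
    XY-differentiated (male-specific allele plus significant between-sex
    F_ST), Y-null (no heterozygous males plus male-only null signal),
    undifferentiated or uninformative, and differentiated loci are summarized
    into chromosomal spans. Includes a seeded simulator of XY genotypes under
    recombination suppression for power and calibration studies, and a
    cross-species microsatellite primer-design workflow (SSR detection,
    conserved-flank alignment, Tm/GC-constrained primer enumeration with
    GTTT pig-tailing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
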