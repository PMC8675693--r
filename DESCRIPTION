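Package: promoterpop
Title: Promoter-Type Haplotypes, Archaic Introgression and Population
    Promoter Activity at the ST8SIA2 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of the ST8SIA2 promoter
    region from phased population panels and archaic (Neanderthal and
    Denisovan) genotypes. Classifies sequences into promoter types at the
    three regulatory SNPs, enumerates and compares haplotypes across
    populations, reconstructs archaic haplotypes by reference-linked
    phasing, scans for shared identical tracts and recombination mosaics,
    screens for archaic-ancestry candidate haplotypes, dates lineages from
    homozygosity tract lengths and accumulated mutations, and summarises
    the population promoter activity (PPA) statistic with its
    archaic-composition enumeration. Includes a seeded synthetic-data
    generator that emulates the study design (an 18-kb low-recombination
    promoter region, planted promoter-type compositions, an introgressed
    archaic donor lineage, and unphased archaic diploids) so every
    analysis can be exercised against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
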