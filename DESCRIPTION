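Package: anthomap
Title: QTL Mapping of Anthocyanin Acylation Traits in F2 Maize Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for small F2 mapping populations
    genotyped by reduced-representation sequencing and phenotyped by HPLC for
    anthocyanin content and acylation. Provides a seeded F2 population
    generator (Haldane meiosis, GBS-style marker maps, call degradation),
    numeric genotype coding with minor-allele-frequency and missing-data
    filters, HPLC-derived trait computation (anthocyanin content by external
    standard, acylation percentage, replicate coefficient of variation,
    kernel-phenotype scores), single-marker and stepwise-covariate regression
    QTL scans with Bonferroni genome-wide thresholds, Type-3
    variance-component decomposition across segregating pigment loci, a
    subsampling power simulation for QTL detectability, and a BAHD
    acyltransferase motif filter for candidate protein sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
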