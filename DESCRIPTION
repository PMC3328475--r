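Package: rrlbsa
Title: Trait-Associated SNP Discovery by Sequencing Reduced-Representation
    Libraries of Phenotypic Bulks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for bulk-segregant analysis (BSA) of
    deep-sequenced reduced-representation libraries (RRLs) in biparental
    mapping populations. Simulates blunt-end restriction digestion of a
    reference genome and ranks enzymes by the genome fraction captured in a
    size-selection window; computes a shattering-resistance-style phenotype
    index from impact-test counts, tests 1:2:1 segregation and assigns
    extreme individuals to susceptible and resistant bulks; filters reads by
    restriction-site residual tag and mean base quality; places reads by
    exact full-length match keeping unique placements; calls biallelic
    "simple SNPs" from per-bulk allele pileups and scores them with a
    two-sided Fisher exact test on the 2x2 bulk-by-allele table; and
    localizes candidate quantitative trait loci (QTL) as tight clusters of
    associated SNPs under a sliding-window scan. A fully seeded F2
    population and read simulator makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
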