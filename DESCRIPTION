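Package: pedtrace
Title: SNP Panel Design, Parentage Assignment and Fingerprinting for
    Traceability of Clonal Breeding Material
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to build and audit a SNP-based traceability system for
    clonally propagated breeding material, as used in tree improvement
    programs that multiply full-sib families through somatic embryogenesis.
    Simulates full-sib progeny from a genotyped parent panel and a mating
    design, ranks biallelic SNPs by informativeness (Fst among families,
    minor allele frequency, random-forest Gini importance), assembles
    assayable panels under one-SNP-per-gene constraints, assigns individuals
    to their cross of origin by Mendelian exclusion and by likelihood,
    quantifies robustness to controlled proportions of missing data and
    genotyping errors, and fingerprints embryogenic cell lines for identity
    monitoring across cryobank and field stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    randomForest,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
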