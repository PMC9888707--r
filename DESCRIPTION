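Package: hlburden
Title: Rare-Variant Burden and Polygenic Analysis of Adult-Onset Hearing
    Loss in EHR Biobanks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for biobank studies of
    adult-onset hearing loss that combine audiometric and electronic
    health record (EHR) phenotypes. Derives a 0-4 degree-of-hearing-loss
    phenotype from pure-tone-average audiograms and phecode billing
    records, qualifies rare deleterious variants by consequence class,
    REVEL score, ClinVar status and population allele frequencies, builds
    per-gene and aggregate allele-count burdens, and runs the association
    machinery: covariate-adjusted linear and logistic burden tests,
    Fisher exact carrier tests, a common-variant scan, genomic-inflation
    diagnostics with permutation-based carrier/MAF threshold calibration,
    Benjamini-Hochberg false-discovery control, and replication
    statistics. Polygenic and burden risk scores are evaluated by
    incremental R-squared with bootstrap errors and top-decile odds
    ratios. A synthetic-cohort generator with known ground truth
    (liability-scale phenotype, misclassified phecode labels, partial
    audiogram coverage) makes every stage testable without access to
    protected biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
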