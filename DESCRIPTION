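Package: pgxkit
Title: Offline Pharmacogenomics Genotype Annotation and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches individual and cohort diploid genotypes against a
    drug-response knowledge base of variant-drug associations (efficacy,
    dosage, toxicity; PharmGKB-style evidence tiers; FDA biomarker-label
    flags). Parses multi-sample VCF v4.2 and four consumer-array genotype
    dialects (23andMe, Affymetrix, deCODEme, Family Tree DNA) into a
    normalized per-sample call table, joins calls to the knowledge base by
    rsID and exact canonical genotype, and produces individual HTML or
    Markdown reports, tri-partite gene-drug-category interaction networks,
    and population-level group statistics (sample-by-gene and sample-by-drug
    count tables, per-population genotype and allele frequencies, burden
    summaries). Includes a Hardy-Weinberg cohort simulator with exhaustive
    ground truth so every component is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    jsonlite,
    xml2,
    yaml,
    vcfR,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
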