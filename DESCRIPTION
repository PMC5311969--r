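Package: honeyforage
Title: Honey DNA Metabarcoding Analysis of Honey Bee Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for plant DNA metabarcoding of honey: merges
    paired-end rbcL amplicon reads, assigns them to plant taxa by exhaustive
    local alignment against a reference library with lowest-common-rank
    collapsing of tied top hits, applies a regional checklist filter, and
    derives per-hive plant composition, major/minor forage classes, richness
    and Simpson diversity. Floral-survey tables are joined to honey
    compositions to quantify use versus availability, per-zone flowering
    density and phenology concordance, with exact small-sample statistics
    (Spearman rank correlation, Mann-Whitney U by enumeration, r-by-c
    Fisher's exact test). A synthetic-data generator produces hierarchical
    reference libraries, read sets with known mixture proportions and
    two-month floral surveys so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    readr,
    stringi,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
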