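Package: famvar
Title: Family-Based Rare-Variant Analysis for Multiplex Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for rare-variant analysis in extended, densely affected
    pedigrees sequenced by whole-exome sequencing. Provides variant-level
    annotation (rarity, worst-consequence ranking, combined PolyPhen-2/SIFT
    pathogenicity scoring, likely gene-disruptive and brain-expression flags),
    sharing-based classification of potentially etiologic versus likely
    neutral variants, covariate-matched random-gene-set enrichment with an
    empirical resampling null, per-subject disruptive-variant burden and
    age-of-onset analysis, trio de novo detection from Mendelian errors,
    deletion inference from runs of Mendelian inconsistency, pairwise
    identity-by-descent relationship checks, and a gene-dropping pedigree
    simulator that generates the study designs these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
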