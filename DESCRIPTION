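Package: svconcord
Title: Structural Variant Callset Concordance and Clinical Performance
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares structural variant (SV) callsets from two sequencing
    platforms applied to the same samples, using type-stratified reciprocal
    overlap matching with separate breakend-proximity matching for
    translocations. Parses Manta-dialect SV VCFs (including breakend pairing
    via MATEID), classifies calls into the ten routinely assayed multiple
    myeloma cytogenetic events (IGH translocations and arm-level gains and
    losses), evaluates detection against FISH truth labels with
    sensitivity/specificity and ROC/AUC, annotates calls against an SV
    hotspot catalog with per-sample burdens, and applies a somatic
    short-variant filter cascade with per-rule accounting. A synthetic-data
    generator emulates the platforms' statistical signatures so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
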