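Package: chromstage
Title: Chromatin Architecture Statistics for Staged Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tidy toolkit for comparing chromatin architecture across samples and
    developmental stages from binned Hi-C contact maps: distance-decay p(s) curves and
    their Jensen-Shannon divergence, A/B compartment PC1 profiles with AA*BB/AB^2
    compartment strength and saddle plots, compartment-domain segmentation with
    superdomain (>10 Mb) coverage statistics, insulation-score TAD boundary calling with
    aggregate TAD/boundary statistics and cross-assembly conservation tests against
    shuffled nulls, distance-stratified binomial loop calling with convergent-CTCF
    filtering and aggregate peak analysis, and inter-homolog contact profiling for
    allele-tagged data. Ships a synthetic Hi-C generator that plants known decay,
    compartment, TAD, loop, and allele structure so every statistic can be validated by
    parameter recovery at desk scale.
License: MIT
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
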