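Package: ncmtools
Title: Neutral Community Model Fitting and Assembly Statistics for
    Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stochastic versus deterministic assembly of microbial
    communities from OTU/ASV count tables. Fits the Sloan neutral community
    model (beta-distribution occupancy-abundance curve) by bounded
    least-squares estimation of the migration parameter m, reports Nm and the
    coefficient of determination, and partitions taxa into neutral,
    above-prediction and below-prediction fractions using Wilson score bands.
    Ships the surrounding workflow: count-table input/output, rarefaction and
    rank aggregation, alpha diversity, Bray-Curtis/NMDS ordination, Mantel and
    partial Mantel tests against physicochemical metadata, one-way ANOVA with
    LSD compact letter displays, core-taxon (Venn) and network summaries, and
    a synthetic generator of neutral, drift-simulated and environmentally
    filtered communities for calibration and power analysis.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
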