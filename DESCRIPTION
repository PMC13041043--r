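Package: fjordflux
Title: Water-Mass Classification, Nutrient Mixing Budgets and
    Nitrogen-Cycle Community Analysis for Arctic Fjord Transects
Version: 0.1.0
Authors@R:
    person("Fjordflux", "Developers", email = "fjordflux@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of fjord-to-shelf
    hydrographic and biogeochemical transects: classification of CTD
    records into named water masses from temperature-salinity-density
    envelopes; station-median nutrient statistics with Mann-Whitney
    tests, Benjamini-Hochberg correction and bootstrap confidence
    intervals; Model II (standardized major axis and Deming) mixing
    diagram regressions; two-endmember conservative-mixing source/sink
    estimation; taxa-table community analysis (relative abundance,
    nitrifier guilds, richness, Bray-Curtis, non-metric multidimensional
    scaling, PERMANOVA, dispersion homogeneity); and single-copy-gene
    normalization of metagenomic gene coverage into Average Genomic Copy
    Numbers.  A synthetic-data module generates coherent two-transect
    studies with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
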