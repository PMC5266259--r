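Package: cytopop
Title: Identifying Bacterial Populations in Synthetic Communities from Flow Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving the composition of synthetic bacterial
    communities from multiparametric flow cytometry data. Single-population
    (axenic) measurements are denoised by reproducible polygon gating in
    arcsinh-transformed fluorescence space and aggregated into labelled
    in silico communities, on which single-cell classifiers (linear
    discriminant analysis and random forests) are trained to predict the
    population of origin of individual cells. The package recovers
    relative-abundance gradients, scans classifier performance against
    community richness, propagates flow-cytometric counting error into
    Hill-diversity (exponential Shannon) confidence intervals, reads and
    writes FCS 3.0/3.1 list-mode files, and simulates ground-truth-labelled
    multi-population datasets with controllable overlap, replicate drift and
    debris noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
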