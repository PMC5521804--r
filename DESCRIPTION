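Package: phytoPLS
Title: Chemometric Modelling of Phytocomplex Antioxidant Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links fruit metabolite profiles to in vitro antioxidant capacity.
    Fits Trolox calibration curves for FRAP and ABTS plate assays and converts
    absorbances to Trolox-equivalent antioxidant capacity (TEAC); normalizes
    untargeted LC-MS feature matrices by median fold change; fits NIPALS PLS1
    models with seven-fold cross-validated Q2, VIP-based variable selection,
    response permutation tests and Monte-Carlo stability selection; scores
    depletion experiments on artificial simplified phytocomplexes to classify
    metabolite-class interactions as additive, synergistic or antagonistic;
    and annotates MS/MS fragmentation trees by glycoside neutral losses and
    diagnostic hydroxycinnamic-acid fragments. Includes a synthetic-data
    generator reproducing the cultivar-dominant variance structure of a
    multi-cultivar cherry study design for testing every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
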