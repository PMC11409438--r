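Package: wormscreen
Title: High-Content Screening Pipeline for C. elegans Vulval Induction Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fluorescence-based high-content drug screens that read out
    MAPK/ERK pathway activity from C. elegans vulval development. Includes a
    seeded synthetic plate-image generator with exact ground truth, size- and
    intensity-gated detection of vulval foci and pharynges in GFP well images,
    well-level phenotype scoring (vulvae per adult, percent larvae), Z-factor
    assay-quality statistics and dose-response aggregation, rule-based primary
    hit selection with artifact and toxicity exclusions, and a lin-1
    counter-screen classifier for pathway specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
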