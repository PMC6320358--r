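Package: stressgp
Title: Genomic, Pedigree and High-Throughput Phenotyping Based Grain Yield
    Prediction for Stressed Wheat Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for grain-yield prediction in elite wheat
    yield-trial nurseries evaluated under drought and heat stress. Turns
    plot-level alpha-lattice trial data into line-level BLUEs and line-mean
    heritabilities, builds VanRaden genomic (G) and tabular pedigree (A)
    relationship matrices with the standard marker quality filters, and
    predicts yield with univariate GBLUP/ABLUP, a combined two-kernel model,
    a multivariate mixed model that borrows information from correlated
    canopy reflectance (GNDVI) measurements, and an item-based
    collaborative-filtering recommender. Family-aware cross-validation
    designs (k-fold, one-progeny-per-cross, full-sib split, heading-date
    subsets, across-nursery forward/backward schemes) and a breeding
    population simulator with gamete dropping, selfing, and multi-trait
    genetic architecture make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
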