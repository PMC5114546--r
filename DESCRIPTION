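Package: pcnonp
Title: Nonparametric Principal-Component Correction for Population
    Stratification in Rare-Variant Association Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements PC-nonp, a score test for rare-variant association
    that controls population stratification by residualizing both trait
    values and genotype scores on ancestry principal components with a
    quartic-kernel Nadaraya-Watson regression. The smoothing bandwidth is
    selected by minimizing the Kolmogorov distance between genome-wide
    marker p-values and the uniform distribution. Also provides the
    classical comparison tests (uncorrected score test, genomic control,
    linear PC regression), Madsen-Browning weighted regional scores, and
    two cohort simulators: a Balding-Nichols discrete-subpopulation model
    and a structured coalescent on a migration grid, used to calibrate
    type I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
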