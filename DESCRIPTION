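Package: ychope
Title: Individual-Based Simulation of Y-Shredding CRISPR Gene Drives
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stochastic individual-based models of CRISPR homing gene drives
    that carry a Y-chromosome "shredding" cargo for the suppression and
    eradication of closed pest mouse populations. Implements germline homing
    with multiplexed guide RNAs under a simultaneous-cutting model, the
    evolution of NHEJ-derived resistance alleles, coding (haploinsufficient)
    versus non-coding drive placement, zygotic Y-shredding that converts XY
    males into sub-fertile XO females, a polygynous mate-allocation scheme
    with density-dependent logistic survival, and a Y-linked X-shredding
    comparator drive. Includes replicate experiment drivers, eradication
    threshold searches, and a global sensitivity analysis built on Latin
    hypercube sampling with a boosted-regression-tree emulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
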