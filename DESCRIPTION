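Package: ctcompare
Title: Cross-Platform Concordance Analysis for MicroRNA qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing microRNA quantification across qPCR
    platforms that differ in reaction volume, pre-amplification and
    dilution. Computes replicate-level variability (CV%, replicate range,
    expression tiers), fidelity scoring at 1/2/3-cycle cutoffs,
    inter-run reproducibility, z-score cross-platform concordance with
    compression slopes, Ward/Mojena/k-means cluster concordance, and
    radar-style biomarker signature comparison. Includes a stochastic
    multi-platform qPCR simulator based on Poisson partitioning of
    template copies at platform-specific reaction volumes, so the whole
    pipeline can be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
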