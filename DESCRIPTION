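Package: optenrich
Title: Simulation and Scoring of Optical-Enrichment Pooled CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-backed implementation of
    optical-enrichment pooled CRISPR screening: synthetic sgRNA libraries and
    cell populations with planted phenotypes, rendered multi-channel
    fluorescence fields with ground truth, nucleus segmentation and size
    measurement, patterned-illumination photoactivation masks with
    multi-intensity activation kinetics, FACS gating and sorting simulation,
    and sgRNA count statistics (phenotypic scores, Mann-Whitney tests against
    nontargeting controls, simulated negative controls, a combined score eta,
    and empirical-FDR hit calling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
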