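Package: tracemid
Title: Mass-Isotopologue Correction and NADPH Active-Hydride Deconvolution for Stable-Isotope Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable-isotope tracing metabolomics: natural-abundance and
    tracer-impurity correction of mass-isotopologue distributions (MIDs) by
    non-negative least squares, labeling-fraction and fractional-enrichment
    metrics, serum-normalized in vivo 13C enrichment, deconvolution of the NADPH
    active-hydride labeling fraction from the NADP+/NADPH isotopologue pair,
    bench-assay arithmetic (serine consumption, ROS, redox ratios, proliferation
    slopes), a forward simulator of tracer cohorts with known ground truth, and a
    peak-table pipeline for El-MAVEN-style isotopologue exports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
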