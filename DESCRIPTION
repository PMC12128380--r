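Package: msremeth
Title: Simulation and Analysis of MSRE-qPCR DNA Methylation Biomarker Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for blood-based DNA methylation biomarker studies that use
    methylation-sensitive restriction enzyme PCR (MSRE-PCR) with gel
    densitometry and quantitative PCR (qPCR) readouts. Provides a synthetic
    cohort generator for case-control designs (paired digested/undigested Ct
    values, band intensity ratios, calibration standards, clinical
    covariates coupled by a Gaussian copula), delta-Ct based methylation
    quantification with standard-curve validation, threshold classification
    with ROC/AUC diagnostics computed from first principles, nonparametric
    association statistics (Mann-Whitney, Kruskal-Wallis with Dunn's post
    hoc, Spearman, linear regression), restriction-site scanning, and a
    reproducible end-to-end pipeline with manifests and delimited-text
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
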