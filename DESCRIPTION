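Package: hrmsqc
Title: Targeted Quality-Control Screening for LC-HRMS Metabolomics Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Targeted quality control for centroided liquid
    chromatography high-resolution mass spectrometry (LC-HRMS)
    metabolomics data. Extracts user-defined target features from mzXML
    runs listed in one or more measurement sequences and reports the
    stability of retention time, mass accuracy (ppm), detector
    sensitivity (feature area) and carbon isotopolog ratio as
    four-zone colour-classified overview tables, per-parameter plots
    and tidy CSV output. Includes molecular-formula and adduct m/z
    computation, ppm-windowed extracted ion chromatograms, continuous
    wavelet transform peak picking, and a deterministic synthetic
    campaign generator with injectable retention-time drift, mass
    drift and sensitivity steps for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
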