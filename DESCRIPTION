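Package: petmtv
Title: Metabolic Tumor Volume Delineation and Response Prediction for FDG-PET
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of FDG-PET scans in pediatric
    Hodgkin's lymphoma: synthetic PET phantom generation with ground-truth
    lesion masks, lesion delineation by background-adapted, relative-maximum
    and fixed-SUV thresholding, extraction of metabolic (SUVmax, SUVmean,
    SUVpeak, MTV, TLG) and heterogeneity parameters (asphericity, gray-level
    co-occurrence texture, cumulative SUV-volume histogram), EuroNet-PHL
    treatment-group assignment and early-response classification, cohort
    simulation, and stratified ROC and diagnostic-accuracy statistics with
    exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
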