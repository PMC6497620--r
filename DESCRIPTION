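Package: urimark
Title: Urinary Dietary Biomarker Discovery from Flow-Infusion
    High-Resolution Mass Spectrometry Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering and validating urinary
    biomarkers of dietary exposure from flow-infusion electrospray
    high-resolution mass spectrometry (FIE-HRMS) fingerprints of spot
    urine samples.  Covers specific-gravity (refractive index)
    normalization, conversion of centroided mzML infusion runs into
    aligned 0.01 amu m/z-bin fingerprint matrices, day-structured
    baseline versus postprandial comparisons with bootstrapped random
    forest / AUC / t-test feature selection and tiered candidate calling,
    accurate-mass adduct and neutral-loss annotation at ppm tolerance
    with Metabolomics Standards Initiative evidence levels, and
    dose-response validation of candidate markers against portion-size
    classified exposure (t tests and Spearman rank correlation).  A
    synthetic free-living food-intervention study generator, with
    dose- and time-dependent marker excretion kinetics, urine dilution
    variation, adduct and isotope peaks and a Gaussian infusion profile,
    makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mzR,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
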