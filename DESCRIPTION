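Package: nmrxai
Title: Explainable Neural-Network Metabolite Profiling from 1H-NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mixture 1H-NMR spectra of aqueous metabolite panels
    (Lorentzian multiplet synthesis, line broadening, sub-gridpoint chemical
    shift perturbation, noise, baseline offsets and interfering singlets),
    trains multi-layer perceptron regressors that map a spectrum to analyte
    concentrations, and explains their predictions with an integrated
    gradients attribution engine built around a reference-compound-only
    baseline. Attribution bundles can be audited quantitatively: completeness
    of attribution sums against predictions, region-of-interest integration,
    cross-analyte overlap compensation, interfering-singlet misattribution,
    and inter-node bias detection via attribution similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
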