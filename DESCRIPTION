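Package: kmdaging
Title: Kendrick Mass Defect Analysis of Sebaceous Fingerprint Lipid Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterizing ambient oxidation of sebaceous
    fingerprint lipids from high-resolution MALDI mass spectra, aimed at
    time-since-deposition estimation. Builds an in silico library of
    ozonolysis and epoxidation products of triacylglycerols,
    diacylglycerols, wax esters, fatty acids and squalene; annotates
    centroided peak lists into heteroatom classes at 2 ppm; computes
    Kendrick mass defect plot data and homologous-series groupings;
    normalizes and subtracts spectra; and extracts aging markers
    (triacylglycerol epoxide ratios, medium-chain fatty acid
    accumulation). A ground-truthed synthetic fingerprint spectrum
    simulator supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
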