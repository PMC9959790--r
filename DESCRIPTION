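Package: honeynmr
Title: Quantitative 1H NMR Profiling and Chemometric Authentication of Honey
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted quantitative 1H NMR analysis of honey and chemometric
    discrimination of its geographic origin. Converts processed 1D proton
    spectra into a 33-component concentration table by region integration
    against a TMSP internal standard, with anomeric-ratio and fructose
    tautomer corrections and limit-of-quantification handling. Provides
    standard-deviation-scaled PCA, PLS-DA with contiguous-block
    cross-validation and threshold classification, one-class SIMCA with a
    95 percent leverage/residual acceptance boundary, replacement-method
    variable selection, volcano statistics, and repeated-split error
    frequency analysis, together with a synthetic spectrum and cohort
    generator for validation of the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
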