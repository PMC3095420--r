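Package: cntdna
Title: Construction and Stability Analysis of DNA-Wrapped Carbon Nanotube Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building atomistic models of single-stranded DNA wrapped
    helically around single-walled carbon nanotubes, scoring and locally
    optimizing the hybrids with a simplified molecular-mechanics potential,
    scanning the DNA binding energy as a function of wrapping angle, and
    generating and analyzing synthetic scanning-tunneling-microscopy
    topographies of the wrapped tubes, including Fourier-based extraction of
    the DNA coiling period and wrapping angle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
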