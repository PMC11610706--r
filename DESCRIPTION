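Package: g4screen
Title: NMR Screening Analysis of a G-Quadruplex Variant Library
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for screening a 496-member mutational variant library of a
    monomeric reference G-quadruplex by 1D 1H NMR. Enumerates the library from
    its design rules (a central-tetrad sub-library and three loop
    sub-libraries), annotates mutational signatures, and assigns rule-based
    spectral classes; generates class-conditioned synthetic imino-region
    spectra, ion-exchange chromatograms and five-activity functional tables;
    preprocesses and clusters spectra; types chromatographic peaks into
    multimeric-state elution windows; and computes renormalised class activity
    profiles with a permutation null for within-class homogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    mclust,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
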