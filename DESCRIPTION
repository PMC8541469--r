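Package: petscatter
Title: Energy-Window Scatter Correction and List-Mode Reconstruction for PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual- and triple-energy-window scatter estimation for list-mode
    positron emission tomography, with a desk-scale Monte Carlo coincidence
    simulator (Klein-Nishina Compton transport in cylindrical water phantoms),
    kernel-density smoothing of line-of-response window counts with a
    Silverman rule-of-thumb bandwidth, per-LOR scatter fraction estimation,
    and list-mode MLEM/OSEM reconstruction with an additive scatter term.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
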