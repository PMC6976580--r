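Package: spinESR
Title: Nitroxide CW-ESR Lineshapes from Orientational Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts continuous-wave ESR spectra of nitroxide spin labels
    from orientational trajectories of the label's principal axes system.
    Implements exact spin-density-matrix propagation with field-modulation
    detection emulation, a Redfield-theory lineshape engine with
    Zeeman-hyperfine cross-correlations, molecular-frame rescaling of the
    overall tumbling, Brownian/cone/jump synthetic motion generators,
    orientational and dihedral correlation analysis, and Voigt-profile
    fitting of first-derivative spectra with peak-to-peak descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, pracma, minpack.lm, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), bio3d, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
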