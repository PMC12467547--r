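Package: headspectra
Title: Spatial-Frequency Analysis of Scalp Potentials on Arbitrary Sensor Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the spatial-frequency content of EEG-like
    scalp potential distributions. Implements a semi-analytical four-shell
    spherical volume-conductor forward model (Legendre series with closed-form
    per-degree surface energies), spatial harmonic analysis (Sphara) via the
    linear-FEM Laplace-Beltrami eigenbasis on triangulated sensor layouts,
    real spherical-harmonic least-squares expansions, spatial Nyquist limits
    of electrode arrays, and the energy-spectrum and sampling-sufficiency
    analyses built on top of these, runnable entirely on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
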