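Package: brachymc
Title: Kerma-Approximation Monte Carlo Dosimetry for an Ir-192 HDR
    Brachytherapy Source
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models a GammaMed Plus style encapsulated Ir-192 high-dose-rate
    brachytherapy source and transports its photons with a kerma-approximation
    Monte Carlo (Klein-Nishina Compton scattering, local photoabsorption,
    10 keV cut) through voxelized heterogeneous slab phantoms and spherical
    water geometry. Scores dose to medium with analog deposition or a
    track-length kerma estimator, extracts the TG-43 U1 brachytherapy
    dosimetry parameters (dose-rate constant, radial dose function,
    anisotropy function), and compares dose profiles via
    geometry-factor-normalised point differences and a 1-D gamma analysis
    with local normalisation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
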