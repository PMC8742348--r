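Package: fcsmorph
Title: Transcription-Factor Binding Dynamics by FCS and 3D Nuclear Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transcription-factor chromatin-binding dynamics from
    single-point fluorescence correlation spectroscopy (FCS) and nuclear shape
    from 3D confocal stacks. Provides a multi-tau photon-count correlator, a
    diffusion plus two-binding-population autocorrelation model with
    constrained multi-start fitting, a Brownian-dynamics photon-trace
    simulator with immobile binding sites, a synthetic 3D nucleus generator
    with analytic ground truth, a denoise/segment/measure morphometry chain
    (median + Rudin-Osher-Fatemi filtering, Otsu segmentation,
    marching-tetrahedra surface area, sphericity), and bootstrap median
    comparison tests for group-level inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
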