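Package: hytrait
Title: Hybrid Retrieval of Crop Traits from Hyperspectral Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for hybrid retrieval of crop biochemical and biophysical
    traits (SLA, LAI, CCC, CWC, FAPAR, FVC) from hyperspectral reflectance.
    Simulates trait-labelled canopy reflectance libraries with a declared
    surrogate radiative-transfer model, optimizes training sets with
    Euclidean-distance-based active learning, trains Gaussian-process
    regressors with an automatic-relevance-determination rational quadratic
    kernel under two spectral dimensionality-reduction strategies (principal
    components or ranked bands from sequential backward band removal), and
    maps traits with per-pixel uncertainty over hyperspectral cubes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
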