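Package: channelprint
Title: Cell-Type Recognition from Single-Channel Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recognize the cell type of origin of a large-conductance
    mitochondrial potassium (mitoBK) channel from short excerpts of
    single-channel patch-clamp current recordings. Provides a Markov gating
    simulator with tissue-specific kinetics for generating labelled synthetic
    recordings, basic kinetic analysis (threshold current via kernel density
    estimation with power-law intersection, open-state probability, Boltzmann
    activation-curve fitting), windowing and piecewise aggregate approximation
    preprocessing, a feed-forward autoencoder for reconstruction-error anomaly
    detection and 2-D latent embedding, cross-validated K-nearest-neighbors
    classification with confusion matrices, and K-means centroid distances in
    the latent space as a measure of class separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
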