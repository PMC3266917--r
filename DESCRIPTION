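Package: triadppi
Title: Sequence-Based Prediction of Protein Interaction Partners
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interaction partners from amino-acid
    sequence alone. Sequences are encoded as conjoint-triad class spectra
    (20 residues reduced to 7 physicochemical classes, 343 triad features),
    pairs are classified with a support vector machine, and decision values
    are converted to posterior probabilities by Platt sigmoid calibration.
    Provides single-query partner search against a protein database,
    direct and indirect (one or two intermediates) pair interaction
    prediction, integration of predicted partners with known interactions
    into a partner network, stratified k-fold cross-validated evaluation,
    and a synthetic proteome/interactome generator with planted, learnable
    sequence signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
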