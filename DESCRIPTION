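Package: molcrnn
Title: Conditional Recurrent Generative Modeling of Molecules for
    Target-Focused Library Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distribution-learning conditional recurrent neural network
    (cRNN) over SMILES strings for designing target-focused virtual
    compound libraries. Provides molecule standardization and descriptor
    calculation on top of Open Babel, SMILES tokenization and one-hot
    encoding, an LSTM encoder/decoder trained with teacher forcing,
    transfer learning from a general corpus to a small bioactive target
    set, Gaussian state-vector regularization, latent-space interpolation
    sampling (linear, spherical, single-point), reconstruction and
    generation rate metrics, Murcko scaffold diversity analysis, and a
    drug-likeness / scaffold-novelty screening funnel with per-stage
    accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
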