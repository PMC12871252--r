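Package: pottsfold
Title: Potts Energy Models from Protein Backbones for Sequence Design and
    Stability Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a residue-pair Potts energy function from a protein
    backbone with a k-nearest-neighbour graph neural network. The encoder
    embeds backbone geometry (radial-basis expanded interatomic distances,
    including virtual C-beta atoms), a single linear head converts edge
    embeddings into Potts self- and pair-energy tables, and an
    autoregressive decoder produces single-site amino-acid distributions
    for sequence generation. Training combines a node negative
    log-likelihood with an edge composite pseudo-likelihood, optionally
    averaged over filtered multiple sequence alignments and with Gaussian
    coordinate noise. Includes Potts-guided local sequence optimization,
    mutation ddG scoring, MSA filtering utilities, synthetic backbone and
    alignment generators, and a lightweight reverse-mode autodiff tape on
    which the trainable network is built.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
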