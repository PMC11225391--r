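Package: promptclm
Title: Prompt-Based Constrained Molecule Generation with Chemical Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constrained de novo molecule generation by prompting a single
    decoder-only chemical language model (CLM). Scaffolds and fragments are
    supplied as SMILES carrying dummy-atom attachment markers "(*)"; the package
    re-roots and reverses SMILES so that an attachment point becomes the last
    atom, prompts the CLM to extend it, and iterates over attachment points to
    perform scaffold decoration, two-fragment linking, and multi-fragment
    linking by likelihood-scored insertion. A REINVENT-style augmented-
    likelihood reinforcement-learning loop adapts the same pre-trained model to
    these tasks and to arbitrary reward functions (validity/uniqueness,
    fingerprint similarity, linker length/linearity/flexibility). Includes a
    compact GRU chemical language model, a seeded synthetic SMILES corpus
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
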