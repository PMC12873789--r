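Package: cyclicdesign
Title: Fixed-Backbone Sequence Design for Head-to-Tail Cyclic Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained toolkit for designing amino-acid sequences
    onto head-to-tail cyclic peptide backbones. Generates filtered ensembles
    of macrocyclic poly-alanine-like backbones by Ramachandran-biased torsion
    sampling with iterative kinematic ring closure, counts backbone-backbone
    hydrogen bonds for length-dependent dataset filters, designs and scores
    sequences with a backbone-graph message-passing neural network that uses
    cyclic relative positional offsets, fine-tunes that model on clustered
    in-silico datasets with perplexity-based checkpoint selection, and
    evaluates designs with backbone RMSD, sequence recovery, uniqueness and
    the P_Near folding-funnel statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    withr,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    bio3d
Config/testthat/edition: 3
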