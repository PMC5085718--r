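Package: mmrsom
Title: Site-of-Metabolism Prediction for CYP3A4/2D6/2C9 via Microsomal
    Metabolic Reaction Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bond-level site-of-metabolism (SOM) prediction for the three
    major drug-metabolizing cytochrome P450 isozymes (CYP3A4, CYP2D6,
    CYP2C9).  Every candidate bond of a substrate, paired with the isozyme
    acting on it, forms a microsomal metabolic reaction system (MMRS); the
    package enumerates MMRS candidates for four biotransformations
    (aliphatic and aromatic C-hydroxylation, N- and O-dealkylation),
    characterizes each with 56 bond descriptors computed under a pH 7.4
    protonation convention (PEOE partial charges, orbital
    electronegativities, polarizabilities, neighborhood topology) plus the
    enzyme identity, screens reliable negatives out of unlabeled bonds by
    cross-validated ensemble voting, and searches a feature-selection by
    classifier grid with backward elimination for one optimal classifier
    per biotransformation.  Fitted models predict per-bond metabolism
    calls for new molecules.  A synthetic molecule-library generator with
    planted, descriptor-separable SOM rules makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    e1071,
    ranger,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse
Config/testthat/edition: 3
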