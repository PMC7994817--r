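Package: pnpcpa
Title: Chemical Diversity and Cell Painting Profile Analysis for
    Pseudo-Natural Product Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the two-track characterization of pseudo-natural
    product (PNP) compound collections. The chemical track covers annotated
    compound ingestion (SMILES/SDF), circular count and bit fingerprints with
    count-Tanimoto similarity, intra- and inter-subclass similarity medians,
    principal-moments-of-inertia shape coordinates, quantitative estimate of
    drug-likeness (QED), a trainable natural-product-likeness scorer, and a
    17-descriptor principal component analysis. The biological track
    normalizes well-level cell-painting feature tables against DMSO controls
    (robust z-scores), aggregates replicates, computes induction percentages,
    correlation-distance biosimilarity, median biosimilarity percentages
    (MBP), induction-window profile selection, profile PCA with a
    cluster-separation score, phenotypic fragment-dominance classification,
    and evaluation of predictively designed compound classes. A seeded
    synthetic plate generator with planted fragment signatures, combination
    interactions and ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
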