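Package: lenalign
Title: Local Alignment of Protein-Protein Interaction Networks with
    Unequally Lenient Connectivity Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects protein complexes conserved between two
    protein-protein interaction (PPI) networks by a dividing-and-matching
    local alignment strategy. One network is partitioned into candidate
    subnetworks (from a known complex catalogue or a bundled Markov
    clustering), cross-network protein mappings are propagated by an
    unbalanced bi-random walk seeded with bidirectional BLAST homology,
    and conserved module pairs are grown under separate path-length
    leniency bounds for each network. Includes overlap-score based
    matching against reference complex catalogues (precision, recall,
    F-measure, coverage rate), Resnik semantic similarity over the Gene
    Ontology for functional-relevance scoring, and a synthetic generator
    of paired networks with planted conserved complexes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
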