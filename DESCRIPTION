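Package: HydroBridge
Title: Water-Mediated Hydrogen-Bond Bridges at RNA-Protein Interfaces
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identification and graph-theoretic classification of
    water-mediated hydrogen-bond bridges at the interface of RNA-protein
    complexes. Parses crystal structures (PDB/mmCIF), detects hydrogen
    bonds under geometric criteria (donor-acceptor distance, hydrogen-
    acceptor distance, donor-hydrogen-acceptor angle) natively or by
    ingesting HBPLUS .hb2 output, identifies bridging waters bonded to
    both an amino acid and a ribonucleotide, labels multiplet topologies
    (A_a:w:N_n, cyclic or acyclic), assigns ribonucleotide moieties
    (nucleobase, phosphate, ribose) and nucleobase edges (Watson-Crick,
    Hoogsteen, Sugar), renders systematic bridge names, and aggregates
    survey statistics. Includes a synthetic-fixture generator producing
    small geometrically valid structures for every bridge topology so the
    full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
biocViews: StructuralBioinformatics, ThirdPartyClient, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
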