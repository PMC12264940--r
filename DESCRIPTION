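Package: idpdock
Title: Ensemble Docking and Bound-State Analysis for Intrinsically
    Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Small-molecule docking onto conformational ensembles of
    intrinsically disordered proteins (IDPs). Implements a per-residue
    search-box docking protocol (one cubic box per residue, edge set by
    the ligand radius of gyration, best-scoring pose per conformation)
    and a whole-conformation protocol behind a uniform backend contract,
    together with the downstream characterization of the heterogeneous
    bound ensemble: geometric interaction fingerprints (contacts,
    hydrophobic, charge-charge, hydrogen bonds, aromatic stacking),
    dual-residue contact maps, t-SNE conformational clustering with
    silhouette-driven perplexity selection, frame-matched and
    best-matched ligand RMSD metrics, and min-max normalized docking
    scores with bootstrap uncertainties for relative-affinity ranking.
    Includes a deterministic grid-search mock backend and synthetic
    disordered-peptide fixtures so the full pipeline is testable without
    external docking engines or trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    ChemmineR,
    Rtsne,
    cluster,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
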