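Package: consgrad
Title: Conservation Gradients and Percolation of Selective Pressure in
    Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the evolutionary importance of protein sites with two
    complementary measures: the intrinsic per-residue conservation (normalized
    conservation ranks, dN/dS) and the extrinsic site-induced conservation
    gradient, i.e. the correlation between the conservation of all other
    residues and their Calpha distance from a reference residue. Provides
    structure parsing and residue geometry (side-chain weighted contact
    numbers, distance to the protein center, Shrake-Rupley relative solvent
    accessibility and burial classes, delta-RSA interface detection),
    conservation-score and rate-table ingestion with alignment-based
    annotation transfer, per-protein conservation-percolation correlations,
    packing-covariate residualization, binned trends, functional-site subset
    resampling, within-protein concordance analysis with exact binomial
    tests, bootstrap standard errors, and a seeded synthetic-data generator
    that plants distance-decaying conservation fields so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
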