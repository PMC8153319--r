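Package: refstab
Title: Reference Gene Stability Evaluation for RT-qPCR
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Evaluates candidate reference (housekeeping) genes for RT-qPCR
    normalization from raw threshold-cycle (Ct) tables. Implements the geNorm
    expression-stability measure M with iterative exclusion ranking and the
    pairwise-variation rule for the optimal number of reference genes, the
    NormFinder model-based variance decomposition (ungrouped and grouped),
    and the BestKeeper descriptive statistics and index correlation, together
    with a geometric-mean rank consensus, tissue-specific gene-pair selection,
    standard-curve amplification efficiency, relative quantification by the
    delta-delta-Ct method, and a synthetic Ct-data generator with known
    stability structure for validation. Ships the published tissue-level Ct
    summary table for a 19-gene Schima superba candidate panel as a worked
    fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
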