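Package: affinityforge
Title: Curation, Featurization and Assay Modeling for Kinase Inhibitor
    Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for preparing heterogeneous
    kinase-inhibitor activity data for machine learning. Ingests
    ChEMBL-dialect and PKIS2-dialect activity tables into a typed
    protein/ligand/measurement object model, runs a five-stage curation
    cascade (dummy-target removal, unit standardization to the p-scale with
    extreme-value filtering, within-publication collapse, citation
    deduplication, author-overlap deduplication) with a per-stage audit
    report, featurizes systems through composable pipelines (circular
    fingerprints, one-hot SMILES and sequence encodings,
    fingerprint-similarity template selection), maps a latent binding free
    energy to each assay readout through differentiable link functions, and
    serializes ragged feature tensors with per-record metadata to Parquet.
    Ships a synthetic-fixture generator with planted, self-documented
    ground truth so the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    arrow,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
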