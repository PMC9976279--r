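Package: solqspr
Title: QSPR Modelling of Intrinsic Aqueous Solubility with Nested
    Cross-Validation and Chemical-Space Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for descriptor-based modelling of intrinsic aqueous
    solubility (log10 molar log(S) at 298 K) of drug-like small molecules.
    Curates SMILES/log(S) tables (salt stripping, InChI deduplication,
    size and flexibility filters), computes 2D descriptor panels and Morgan
    fingerprints, trains Random Forest and feed-forward neural-network
    regressors under a 50-resample nested cross-validation protocol, scores
    predictions with an RMSE = sqrt(SDEP^2 + bias^2) error decomposition,
    audits training/testing chemical-space overlap with Tanimoto
    distributions, Bemis-Murcko scaffolds and thresholded similarity
    graphs, and attributes model behaviour to molecular fragments with a
    counterfactual mutation procedure. Includes a synthetic molecule-library
    generator with a known structure-to-solubility ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
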