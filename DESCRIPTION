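Package: ilisr
Title: Local Interface Confidence Scoring and Network Analysis of Predicted Protein Complexes
Version: 0.1.0
Authors@R:
    person("ilisr", "authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores AlphaFold-Multimer dimer predictions with local
    interface-confidence metrics (LIS, cLIS, iLIS, ifPAE, pDockQ and
    companions), profiles per-residue interface frequencies (LIR/cLIR)
    across prediction partners, calibrates classification thresholds at
    fixed false-positive rates on benchmark score tables, tests missense
    alleles for enrichment at predicted interfaces with trend and
    within-gene permutation statistics, and decomposes evidence-supported
    protein-protein interaction networks by recursive permutation-validated
    Leiden clustering. Includes seeded synthetic-fixture generators for
    every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
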