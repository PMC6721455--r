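Package: mirep
Title: Evaluating miRNA Target Predictions by Dual-Luciferase Reporter Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a reporter-assay workflow for
    evaluating microRNA (miRNA) target predictions. Covers seed-site
    scanning and Bartel seed-type classification (8mer, 7mer-m8, 7mer-A1,
    6mer) on 3' UTR sequences, reporter-insert design (MRE-centered ~500 nt
    fragments, clustered-site handling, NheI/XhoI restriction screening),
    normalized repression statistics from firefly/Renilla luminescence
    (R0, R1) with Student t confirmation calls and summary tabulation,
    sequence and thermodynamic features of confirmed targets (windowed AU%,
    distance-weighted local AU content, nearest-neighbor secondary-structure
    and miRNA:MRE duplex free energies, seed-pairing stability), and the
    downstream association analyses (Pearson correlations with prediction
    scores and endogenous expression, one-sided Kolmogorov-Smirnov seed-type
    comparisons, fold-change analysis). A deterministic synthetic-data
    generator emulates the assay's statistical structure so the whole
    pipeline runs and is validated without access to raw measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    dplyr,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
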