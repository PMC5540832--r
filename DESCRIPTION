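Package: psyconn
Title: Structural Connectome Classification of Attenuated Psychotic Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discriminating clinical subgroups from
    structural brain connectomes. Reads per-subject streamline-count and
    streamline-length matrices over a fixed parcellation, normalizes and
    binarizes them, computes weighted and binary graph-theory measures
    (characteristic path length, efficiency, clustering, modularity,
    small-world index, betweenness centrality, strength), consumes
    tract-wise diffusion features (FA, AD, RD), screens features with
    Mann-Whitney tests under FDR control, and discriminates groups with a
    Gaussian naive Bayes classifier under leave-one-subject-out
    cross-validation, point-biserial feature ranking, incremental feature
    curves, Wilson score confidence intervals, in-loop covariate
    residualization, and matched-pair bootstrap stability checks. Includes
    a synthetic cohort generator with planted topological and
    microstructural group effects so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
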