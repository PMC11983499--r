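Package: mltctraj
Title: Temporal Multimorbidity Trajectory Mining and Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines temporally ordered multimorbidity trajectories from dated
    first-diagnosis records. Screens condition pairs for association (Fisher's
    exact test with Bonferroni correction) and temporal direction (exact
    binomial test), composes significant directed pairs into shared
    three-condition trajectories, builds an inverse-frequency weighted
    condition network, derives a shortest-path trajectory similarity matrix,
    and clusters trajectories by spectral clustering with Calinski-Harabasz
    model selection. Includes a synthetic electronic-health-record cohort
    generator with planted directed pair dependencies and planted condition
    communities so every pipeline stage is testable against known ground
    truth, plus cluster characterisation (system composition, mortality,
    long hospital stays, causes of death).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
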