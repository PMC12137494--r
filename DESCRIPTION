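Package: coformr
Title: Virtual Coformer Screening for Pharmaceutical Cocrystal Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A quality-by-design screening funnel for pharmaceutical cocrystal
    coformer selection. Computes molecular complementarity descriptors
    (van der Waals volume, minimum enclosing box axes and their ratios,
    fractional polar volume, dipole moment) over an ensemble of API
    conformations, applies pass/fail complementarity screening with an
    optimal-deviancy closeness metric, fits a logistic hydrogen-bond
    propensity model over donor/acceptor site descriptors with geometric
    hydrogen-bond observation extraction, scores heterosynthon versus
    homosynthon formation via a multi-component score, and combines the
    stages into a ranked coformer short-list. Ships a synthetic-data module
    (known-coefficient logistic observations, planted hydrogen-bond
    geometries, toy molecule series) so the whole funnel is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    igraph,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, used for structure parsing
    and 3D conformer embedding.
Config/testthat/edition: 3
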