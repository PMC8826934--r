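Package: ogttpatterns
Title: Temporal-Pattern Features of Postprandial Blood-Molecule Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-subject blood-molecule concentration time
    courses measured around an oral glucose tolerance test (OGTT).
    Provides responder calling by paired tests with Storey q-values,
    dispersion-scaled trajectory normalization, hierarchical clustering and
    principal-component decomposition of mean trajectories into amplitude
    and rate components, inter-individual similarity indices (TPSI, TVRI),
    an inter-molecule similarity index (TPSM) with correlation-threshold
    network analysis (connected components, betweenness centrality,
    group-normalized degree), per-subject incremental AUC and half-AUC time
    features, and a synthetic postprandial cohort generator with known
    ground truth for validating every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
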