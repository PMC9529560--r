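Package: vrascreen
Title: Virtual Screening and Viscosity Analysis for Antibody Formulation Excipients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational screening cascade for discovering viscosity-reducing
    agents (VRAs) for concentrated monoclonal-antibody formulations. Implements a
    path-based 1024-bit molecular fingerprint with Tanimoto similarity search and
    fingerprint-space clustering, a transparent pKa-table based charge-group
    calculus at formulation pH, physicochemical and structural-alert filter
    stages, exhaustive dipeptide enumeration with a dual-excipient (buffering plus
    charge) filter, an exponential concentration-viscosity baseline model with
    relative-viscosity classification, descriptor correlation and rule-evaluation
    statistics, and a synthetic-data generator emulating two-antibody viscosity
    studies so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
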