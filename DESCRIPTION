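Package: settlegame
Title: Evolutionary Game Analysis of Cross-Regional Direct Settlement and
    Treatment-Seeking Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-population evolutionary game between patients
    with malignant tumours (cross-regional versus in-area care) and hospitals
    (direct versus indirect cross-regional insurance settlement). Provides the
    payoff model and replicator dynamics, equilibrium enumeration, analytic
    Jacobian with determinant/trace stability classification, a seven-scenario
    taxonomy of evolutionarily stable strategies, trajectory and basin-of-
    attraction simulation on the unit square, and one-parameter sensitivity
    sweeps with switch-threshold detection. All results are returned as tibbles
    with ggplot2 plotting helpers and broom-style tidiers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
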