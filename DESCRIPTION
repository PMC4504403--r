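Package: accessopt
Title: Optimization and Floating-Catchment Measures of Healthcare Spatial Access
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures potential spatial access over a healthcare network of
    patient communities and provider facilities. Implements the floating
    catchment area family (gravity, E2SFCA, M2SFCA, 3SFCA) together with two
    assignment-based alternatives: a centralized convex quadratic-congestion
    optimization model and a decentralized per-visit user-choice (Nash
    equilibrium) model. Provides per-community access profiles (distance,
    congestion, coverage, composite measures), method-comparison statistics,
    network intervention analysis (adding facilities, scaling capacity), and
    seeded synthetic network generators, including toy systems for analytic
    comparison and a cystic-fibrosis-like national network emulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
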