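Package: confshare
Title: Confidence Sharing and Fisher Information Flows in Collective
    Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulator and analysis library for collective target
    estimation in interacting agent populations.  Implements the
    confidence-sharing interaction rule (inverse-variance weighted
    fusion with an actively communicated confidence scalar), the
    Bayes-optimal reference algorithm on a gridded probability density,
    passive-only constant linear-combination rules, and a Fisher
    information framework (Fisher-deviation, Fisher channel capacity,
    Cramer-Rao and convergence-time bounds) used to measure how close
    each algorithm comes to the optimal accuracy.  Includes an exact
    provenance-based variance auditor for linear update rules, named
    simulation scenarios, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
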