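Package: socialFT
Title: Forward-Thinking Models of Social Controllability in Iterated
    Ultimatum Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates two-condition iterated ultimatum-game environments
    (choice-contingent "Controllable" offers and choice-independent
    "Uncontrollable" offers), implements an n-step forward-thinking
    responder model combining Rescorla-Wagner norm adaptation, a
    deterministic greedy rollout over hypothetical future offers, and a
    softmax choice rule, and provides per-subject bounded maximum-likelihood
    fitting, information-criterion comparison across planning horizons,
    parameter- and model-recovery pipelines, and model-agnostic behavioral
    summaries with the associated group tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
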