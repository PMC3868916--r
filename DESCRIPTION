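Package: prioritytag
Title: Priority-Tag Model of Attention Capture in Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the priority-tag account of attention capture by abrupt
    onsets in serial self-terminating visual search. Provides closed-form
    expected-comparison predictions for mixed and blocked search designs, an
    exhaustive enumeration oracle and a trial-level stochastic search
    simulator, synthetic reaction-time experiment generation matching three
    classic onset-search designs, and regression-based selection of the
    priority-set capacity from reaction-time data, including per-participant
    R-squared comparison with a repeated-measures ANOVA and LSD post-hoc
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
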