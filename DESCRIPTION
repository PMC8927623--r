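Package: cdlsentinel
Title: Contextual Defeasible Logic for Multi-Agent Health Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based monitoring toolkit built around a propositional
    defeasible-logic proof engine (strict, defeasible and defeater rules with
    a superiority relation), a multi-context system in which independent
    knowledge sources exchange conclusions through prioritized mapping rules,
    and an agent-based simulator of a smart-home / smart-hospital patient
    monitoring scenario. Includes a synthetic physiological sensor-stream
    generator, a conflicting-rule-set alert algorithm with authority routing
    and halt-flag semantics, and a finite-trace temporal property checker
    (globally/eventually operators, ask-tell protocol pairing, and a
    danger-level calculus).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
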