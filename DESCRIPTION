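Package: pairperm
Title: Matched-Pair Permutation Inference for Group-Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis tools for matched-pair group-randomized
    trials with binary endpoints, modelled on school-based smoking-cessation
    studies. Derives prolonged-abstinence and sustained-progress endpoints
    from coded survey items across baseline and two follow-up waves;
    constructs matched pairs of clusters from baseline covariates and
    randomizes within pairs; performs randomization-based permutation tests
    (exact enumeration or Monte Carlo) with confidence intervals by test
    inversion, stratified adjustment, subgroup pair-exclusion, and
    relapse/delayed-abstinence transition tables; and simulates matched-pair
    cluster trials with controllable intraclass correlation for validation
    and power estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
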