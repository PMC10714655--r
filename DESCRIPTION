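Package: fcmlearn
Title: Individual-Level Fuzzy Cognitive Maps for Intervention Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns one signed, weighted causal network (a fuzzy cognitive
    map) per individual from short longitudinal measurements of behavioural
    determinants, using a trajectory-fitting real-coded genetic algorithm.
    Converts expert linguistic ratings of intervention strength into numeric
    causal weights through triangular membership functions, endorsement
    activation, family-max aggregation and centroid defuzzification.
    Simulates continuous-exposure intervention scenarios to equilibrium with
    a sigmoid transfer function and reports per-determinant percent change
    at the individual and the cohort level. Includes a synthetic-cohort
    generator emulating Likert-measured determinant panels, file readers and
    writers for trajectories, weight matrices, ratings and scenarios, and a
    command-line pipeline tying the steps together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
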