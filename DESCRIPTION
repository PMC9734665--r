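Package: sjrecal
Title: Simultaneity Judgment Modelling and Audiovisual Temporal
    Recalibration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing audiovisual simultaneity-judgment (SJ)
    experiments. Implements a two-criterion psychometric observer model
    fitted to per-SOA binomial response counts by maximum likelihood,
    estimation of the point of subjective simultaneity (PSS) and the
    window of subjective simultaneity, a deviance-based participant
    screen against a single-cumulative-Gaussian null model, group-level
    inference for paired adaptation designs (paired t tests with dz,
    2x2 repeated-measures ANOVA with partial eta squared and simple
    main effects, noncentral-t power mathematics), and a synthetic-data
    generator that emulates adaptation/test designs used to study
    audiovisual temporal recalibration, so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
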