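Package: glucolog
Title: Blood Glucose Self-Monitoring Analytics, Incentive Engine, and
    Trial Simulation for Adolescent Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing self-monitored blood glucose (SMBG)
    downloads from meters and insulin pumps in adolescent type 1 diabetes:
    parsing and merging multi-device exports, cutting 50-day clinic review
    windows, per-context in-target summaries, detection of consecutive
    out-of-range trends with a resolution lifecycle, a point-based reward
    and engagement engine, hypoglycemia episode grouping, availability-
    corrected SMBG frequency, questionnaire scoring arithmetic (SCI, DQOLY,
    DFRQ), a synthetic two-arm cohort generator with stratified block
    randomization, and the matching trial statistics layer (power
    calculation with dropout inflation, baseline balance tests, a profiled
    restricted-maximum-likelihood random-intercept longitudinal model,
    exploratory regressions, and engagement analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
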