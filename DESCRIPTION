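Package: cogbattery
Title: Smartphone Cognitive Test Battery Generation, Scheduling and Validation Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and scores the five smartphone-adapted cognitive tests of a
    remote-monitoring battery (word-list recognition memory, a four-part trail making
    test, a three-panel Stroop colour-word test, a go/no-go reaction-time test with a
    startle probe, and a letter n-back test), reproduces the study's reminder calendar
    and its within-one-week adherence statistic, simulates synthetic respondents with a
    shared latent ability, practice effects, adherence decay and dropout, and implements
    the validation analytics: Spearman relative validity with mid-rank tie handling,
    z-score Bland-Altman agreement, mistake-filtered and mean-of-attempts sensitivity
    analyses, and random-intercept/random-slope linear mixed models of practice effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
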