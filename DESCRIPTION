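Package: chronocog
Title: Chronotype, Free-Living Physical Activity and Time-of-Day Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for free-living studies of chronotype, physical activity and
    cognitive performance. Scores the 13-item Composite Morningness Questionnaire
    and assigns quintile chronotype groups; extracts activity features from
    wrist-accelerometer 60-second epoch series (wear-time screening, trailing
    60-minute rolling area under the curve, daily peak-activity times with
    circular averaging, 7-day total activity); cleans trial-level cognitive task
    logs into per-session outcomes with reaction-time validity and engagement
    filters; and fits the study's inference layer (one-way ANOVA with Bonferroni
    post-hocs and partial eta squared; random-intercept linear mixed models with
    a chronotype-by-time-of-day interaction and covariate control). A synthetic
    cohort generator with chronotype-dependent activity rhythms and
    reaction-time outcomes supports end-to-end testing, parameter-recovery and
    type-I-error simulation without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    zoo,
    lme4,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
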