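Package: kapsleep
Title: Rest-Activity Estimation from Smartphone Keyboard Inactivity and Sleep Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for approximating rest-activity patterns from smartphone
    keyboard event streams and comparing them with morning sleep-diary reports.
    Implements the keystroke-absence-period (KAP) algorithm (longest gap in
    keyboard activity between 7 PM and 3 PM the next day, with last/first
    keystroke, KAP duration and midpoint as rest-activity proxies), derivation
    of the corresponding diary metrics (bedtime, try-to-sleep, sleep onset,
    midsleep, offset, out-of-bed, total sleep and bed periods), and the
    multilevel machinery used to compare the two modalities: intraclass
    correlations from unconditional models, null-hypothesis and TOST
    equivalence tests on stacked modality data, repeated-measures Bland-Altman
    summaries, cluster-mean-centered moderation models, random-slope models,
    and cross-level trait moderation (chronotype, sleep quality, trait
    self-control). A seeded synthetic cohort generator with a ground-truth
    circadian sleep model makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
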