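Package: chestgait
Title: Gait Parameter Extraction and Validation Statistics for Chest-Worn Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting spatiotemporal gait parameters from a single
    trunk-worn (chest or lumbar) tri-axial accelerometer and for assessing the
    agreement of the resulting endpoints between devices. The extraction
    pipeline detects walking bouts from 3-second windows, locates initial and
    final foot-contact events with a continuous wavelet transform of the
    integrated vertical acceleration, and estimates stride length with the
    inverted pendulum model. The statistical layer provides Bland-Altman
    limits of agreement, intraclass correlation ICC(2,1) with F-based
    confidence bounds, error metrics, test-retest reliability, mixed-effects
    device-by-task models with type-III ANOVA and least-squares-mean
    contrasts, and paired comparisons of walking-bout statistics. A
    synthetic-data module simulates complete two-visit gait studies with
    ground-truth events so that every stage is testable without access to raw
    sensor recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pracma,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
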