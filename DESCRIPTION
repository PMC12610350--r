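Package: wristrep
Title: Psychometrics of Wrist-Worn Inertial Sensor Measures of Task Repetitive Practice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess upper-extremity task repetitive practice from raw
    tri-axial wrist gyroscope and accelerometer streams. Provides a synthetic
    session generator with known ground truth, delimited-text sensor stream
    input/output and validation, automated trial segmentation by
    baseline-relative velocity thresholds, per-trial outcome measures
    (duration, average total angular velocity, total standard deviation of
    acceleration), and the psychometric battery used to evaluate such
    measures: two-way mixed-effects absolute-agreement intraclass correlation
    with F-based confidence intervals, normality-gated repeated-measures
    ANOVA or Friedman omnibus tests with partial eta squared or Kendall's W,
    and Bonferroni-corrected paired comparisons with Cohen's d.
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
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
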