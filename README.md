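# wristrep

Psychometrics of wrist-worn inertial sensor measures of upper-extremity
task repetitive practice.

Repetitive practice of functional tasks (lifting a cup, handwriting, tying
a shoe) drives motor recovery after stroke, but most of it happens at home,
unobserved. A consumer wrist monitor recording tri-axial angular velocity
(degrees/s) and acceleration (m/s²) at 62 Hz can document that practice —
if simple measures derived from the raw stream are reliable and valid.
`wristrep` implements that whole chain for researchers evaluating such
measures:

* **Signal layer** — strict CSV I/O for raw exports, stream validation
  (sampling gaps, monotonicity), rectification into absolute-value
  channels and the total angular velocity trace
  $|V_x| + |V_y| + |V_z|$.
* **Segmentation** — automated trial start/stop detection by
  baseline-relative thresholds (enter at baseline + 5 MAD of the quietest
  decile of the stream, margin-based hysteresis, boundary refinement),
  with algorithmic flagging and exclusion of ambiguous trials.
* **Measures** — per trial: duration (stop − start), average total angular
  velocity $\overline{|V_x|+|V_y|+|V_z|}$, total SD of acceleration
  $\sigma_x+\sigma_y+\sigma_z$ (signed channels by default), plus
  avg/SD/max/min for all six channels.
* **Statistics** — two-way mixed-effects absolute-agreement ICC, ICC(A,1)
  and ICC(A,k), with McGraw–Wong F-based confidence intervals and
  poor/moderate/good/excellent labels; Shapiro-gated repeated-measures
  ANOVA (Mauchly sphericity, Greenhouse–Geisser, partial η²) or Friedman
  test (tie-corrected χ², Kendall W); Bonferroni-corrected paired t-tests
  (α = 0.05/12 ≈ 0.004) with Cohen's d_z.
* **Synthetic cohorts** — a generator with half-sine burst kinematics,
  log-normal participant/trial effects and known ground truth (windows,
  true measures, true variance-ratio ICC), so every stage is testable
  without access to clinical recordings.

See the methods vignette (`vignettes/wristrep-methods.Rmd`) for the models,
parameter choices, and known limitations.

## Worked example

Simulate a 25-participant study session (4 tasks × 5 conditions: 5/10/20
comfortable repetitions, 10 fast, 10 comfortable repeated; 30-s rests),
segment every raw stream, compute the measures, and run the battery:

```r
library(wristrep)
cfg <- run_config(mode = "synthetic",
                  cohort = cohort_config(n_participants = 25, seed = 1))
report <- run_pipeline(cfg)

report$reliability[report$reliability$task == "cup", c(2:4, 6:9)]
#>                measure    form  n   icc ci_lower ci_upper    label
#>             duration_s  single 25 0.679    0.392    0.845 moderate
#>  avg_total_ang_vel_dps average 25 0.896    0.766    0.954     good
#>     total_sd_accel_ms2 average 25 0.896    0.765    0.954     good

report$omnibus[report$omnibus$task == "cup", c(2, 4, 5, 8, 13)]
#>                measure     test statistic        p effect_size
#>             duration_s rm_anova  270.7792 7.20e-27     0.91858
#>  avg_total_ang_vel_dps rm_anova    0.0919 9.12e-01     0.00382
#>     total_sd_accel_ms2 rm_anova    0.0613 9.41e-01     0.00255

report$paired[report$paired$task == "cup", c(2, 8:10, 12, 15, 16)]
#>                measure mean_diff sd_diff     t        p cohens_d significant
#>             duration_s   -10.528   5.356 -9.83 6.88e-10    -1.97        TRUE
#>  avg_total_ang_vel_dps    40.606  27.202  7.46 1.05e-07     1.49        TRUE
#>     total_sd_accel_ms2     0.577   0.386  7.47 1.04e-07     1.49        TRUE

report$exclusions$label
#> [1] "0/500 (0.0%)"
```

Reading the cup-task rows: repeated 10-repetition trials agree well across
the session (ICC(A,k) ≈ 0.90, "good"; duration, rated as a single
measurement, is lower at 0.68). Repetition count moves duration enormously
(F ≈ 271, η² ≈ 0.92) while leaving speed and force variation untouched
(p ≈ 0.9) — more repetitions take longer but are performed the same way.
The fast-pace contrast shifts all three measures (trials ≈ 10.5 s shorter,
≈ 41 degrees/s faster, acceleration SD up 0.58 m/s²; all significant at
α = 0.004). No trial was flagged ambiguous in this clean synthetic cohort.

`render_report(report, "markdown", "out/")` writes the three tables with
the usual footnote markers; `"csv"` and `"json"` renderings carry the full
schema. A thin command-line wrapper with `simulate` / `run` / `analyze`
verbs lives at `inst/cli/wristrep-cli`.

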