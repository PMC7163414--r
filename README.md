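# gazerel

Can eye tracking replace manual annotation when building models that predict
which parts of an ICU patient's record a physician will actually want to see?

Systems that prioritize the display of relevant medical-record data need
per-item training labels: for each data item (all blood-glucose
measurements, a medication's administrations, a ventilator setting, ...),
did the physician seek it while preparing for rounds? Labels can be
collected explicitly — the reviewer checks a box next to each relevant item
— or implicitly, by translating an eye tracker's gaze stream into per-item
dwell times and thresholding. `gazerel` implements both labeling routes and
the machinery to compare them, end to end, on synthetic ICU data with known
ground truth:

- **Synthetic ICU cohorts and review sessions.** Patient cases with nine
  variable categories as time-stamped series, a latent logistic relevance
  model over three case summaries (measured in the last 24 h, latest value
  abnormal, diagnosis match), and simulated review sessions: a ~60 Hz gaze
  stream over a scrolling interface (element rectangles move between layout
  snapshots), checkbox selections with flip noise, and session-loss
  mechanisms (incomplete gaze capture, skipped selection task).
- **Dynamic area-of-interest gaze processing.** Each valid gaze sample is
  attributed to the element whose rectangle (from the layout snapshot in
  force at that timestamp) contains it, under half-open pixel containment;
  per-item dwell accumulates across revisits. An item is labeled *positive*
  when dwell ≥ 250 ms (the average reading fixation), *negative* below, and
  *absent* when the case has no data for it.
- **Clinical time-series featurization.** A fixed-width grouped vector per
  case: 35 features per laboratory test and vital sign (first, most recent,
  highest, lowest values, last-two difference, and 30 more), 31 per
  ventilator setting, 9 per medication, 4 per culture and procedure, 2 per
  intake/output variable, 1 per atemporal variable. Preprocessing removes
  constant features, merges duplicates, and produces two complete variants:
  median/mode-imputed and regression-imputed.
- **Per-item model selection.** For each eligible target (> 3 positive
  labels), feature groups are screened per predictor variable (kept when
  cross-validated AUROC > 0.55), then six candidates — {median, regression
  imputation} × {L2-penalized logistic regression, RBF support vector
  classifier, random forest} — are compared by stratified 5-fold CV and the
  winner is refit on all training cases.
- **Paired evaluation.** Each target's manual-trained and gaze-trained
  models are scored on an evaluation cohort (manual selection is the gold
  standard; absent cases excluded per target): AUROC with 95% paired
  bootstrap CIs, per-pair significance from the difference CI, and a
  cross-target paired Wilcoxon signed-rank test.

The AUROC is the rank statistic `P(score_pos > score_neg) + ½·P(tie)`; the
paired bootstrap resamples evaluation cases, applying the same resample to
both models of a pair.

## Worked example

```r
library(gazerel)

vc <- c(vitals = 2, ventilator = 1, labs = 3, medications = 2,
        procedures = 1, cultures = 1, intake_output = 1,
        demographics = 6, diagnosis = 1)
rc <- run_config(
  training   = sim_config(n_cases = 60L, variable_counts = vc),
  evaluation = sim_config(n_cases = 12L, variable_counts = vc),
  n_reviewers = 2L, B = 500L, seed = 11L)
study <- run_study(rc)
print(study)
#> Gaze-vs-manual relevance study
#>   training: 60 sessions, 20 QC-discarded, 40 cases used
#>   evaluation: 24 sessions, 2 QC-discarded, 22 used
#>   models trained: 11 manual, 11 gaze; 11 shared pairs evaluated
#> Paired evaluation: 11 target pairs
#>   mean AUROC: manual 0.562, gaze 0.543
#>   significant pairs: 1 favor manual, 0 favor gaze (alpha from difference CI)
#>   paired Wilcoxon signed-rank: V = 25, p = 0.52
```

Sixty simulated review sessions lost 20 to quality control (incomplete gaze
capture or a skipped selection task); 40 cases trained 11 model pairs, and
22 evaluation sessions scored them. Mean AUROCs near 0.55 are expected at
this toy scale — 40 noisy training labels per target; the parameter-recovery
test suite shows both label sources reaching held-out AUROC ≥ 0.75 for most
targets at n = 500. The Wilcoxon p of 0.52 says the manual-trained and
gaze-trained model families performed similarly across targets —
the study's central question. `summary(study)` prints the per-target table
(AUROCs with CIs, sorted by manual performance); `plot(study)` draws the
manual-vs-gaze AUROC scatter with the diagonal and significance markers.

Lower-level entry points: `generate_cohort()`, `simulate_session()`,
`compute_dwell()`, `derive_gaze_labels()` / `derive_manual_labels()`,
`qc_session()`, `assemble_matrix()`, `preprocess_features()`,
`relevance_fit()` (with `print`/`summary`/`predict`/`coef` methods),
`auroc()`, `bootstrap_paired_ci()`, `wilcoxon_signed_rank()`,
`build_report()`. `run_stage()` runs the same pipeline against a directory,
stage by stage, writing plain-text artifacts (case JSON, gaze CSV, layout
JSON Lines, label CSVs, matrix CSVs with JSON schema sidecars) and
checksummed reproducibility manifests; reruns are byte-identical.

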