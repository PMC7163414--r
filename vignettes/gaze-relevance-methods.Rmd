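---
title: "Methods: gaze-derived versus manual relevance labels for ICU record review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-derived versus manual relevance labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A record-review interface that highlights the data a physician will want to
see needs, for every displayable *data item* (all glucose values, one
medication's administrations, a ventilator setting...), a supervised model
of its relevance to the current case. Training labels can be collected by
asking reviewers to check boxes (manual selection) or inferred from an eye
tracker: if the reviewer's gaze dwelt on an item's screen region long
enough, the item was presumably examined. The package implements both
labeling routes and a paired comparison of the models they produce, on
synthetic data where the true relevance process is known.

## The synthetic study

### Patient cases

A cohort is drawn from a fixed variable inventory spanning nine categories
(vital signs, ventilator settings, laboratory tests, medications,
procedures, microbiology cultures, intake/output, demographics, diagnosis).
The default inventory — 14 vitals, 9 ventilator settings, 20 labs, 30
medications, 10 procedures, 5 cultures, 7 intake/output variables, 6
demographics, 1 diagnosis — is a scaled-down rendering of a real ICU data
dictionary; tests and the acceptance script use smaller inventories
(stated below) so the full pipeline runs in minutes on one CPU. Diagnoses
alternate between acute kidney failure and acute respiratory failure, so
cohorts are balanced to within one case. Each time-series variable is
present in a case with probability `1 - missing_rate` (default 0.2); an
absent variable has no series at all, which later drives the "absent
target" exclusion rule. Timestamps run from admission (0) to the
prediction time (default 2880 min = 48 h).

### The latent relevance model

Relevance is generated, per item, by a logistic model over three case
summaries, each exactly recoverable from the case data:

* `recent` — the item was measured within 24 h of prediction time
  (generated true with probability 0.7);
* `abnormal` — the latest value lies outside the item's reference range
  (probability 0.35);
* `diagnosis` — the case diagnosis matches the item's affinity
  (probability 0.5 under balanced cohorts).

The default coefficients (intercept −4.40; 2.52, 2.49, 2.14) were chosen
once so that the Bayes-optimal scorer (the true probability itself)
achieves AUROC ≈ 0.85 against the realized relevance draws, at a positive
rate of ≈ 0.40. This gives parameter-recovery tests a known ceiling: no
trained model should beat ≈ 0.85, and a sound pipeline should approach it.

### Review sessions

One session simulates one reviewer preparing one case. Layout snapshots
every 2 s place one rectangle (800 × 80 px) per present item in a vertical
list; the page scrolls linearly over the session, so rectangles move
between snapshots and any correct dwell computation must use the snapshot
in force at each gaze timestamp. For each present item, a Bernoulli draw at
its true relevance probability selects the intended-dwell mode: lognormal
with median 1200 ms (relevant) or 60 ms (irrelevant), sigma 0.5 on the log
scale. The two modes sit clearly on either side of the 250 ms labeling
threshold — under the defaults, fewer than 0.5% of draws land on the wrong
side — so gaze labels are a nearly noiseless readout of the relevance draws,
and their information content can be dialed down by narrowing the mode
separation. Gaze is emitted as fixation bouts at the configured sample rate
(default 60 Hz): consecutive samples inside the item's current rectangle,
then three transition samples outside every rectangle. Manual selections
are the same relevance draws with independent flips (default probability
0.05, our reading of "a reviewer occasionally mis-checks a box"; the
source study does not quantify it). Sessions are marked `gaze_incomplete`
(60% of samples invalidated) with probability 0.2 and `selection_skipped`
(no selection record) with probability 0.06; jointly these discard ≈ 25% of
training sessions, matching the study design's attrition of 178 reviewed
cases to 134 usable ones. Evaluation sessions never use gaze, so only
skipped selections remove them (expected 4 of 72).

What the generator does *not* emulate: saccade kinematics or any
eye-movement physiology, free-text notes, pharmacological structure,
between-reviewer variability, or correlated missingness. Passing tests
therefore show that the pipeline recovers a planted signal through the
full gaze → dwell → label → feature → model → evaluation chain; they do not
certify performance on real ICU data.

## Gaze processing

Coordinates are screen pixels, origin top-left, y down; rectangles are
half-open (`x0 ≤ x < x1`, `y0 ≤ y < y1`), which makes boundary behavior
exact and testable. Each valid sample contributes
`min(next_timestamp − timestamp, max_gap_ms)` to the item whose rectangle
contains it under the latest snapshot at or before the sample; the cap
(default 100 ms) stops tracker dropouts from being credited as dwell; the
final sample contributes the nominal sample period (median inter-sample
gap). Dwell accumulates across revisits — total dwell, not longest visit;
the alternative reading is flagged for sensitivity analysis but not
implemented. The label threshold is **inclusive**: dwell of exactly 250 ms
is positive. The two phrasings in the source material ("longer than" in
the device description, "at least" in the target definition) conflict; the
target-variable definition wins because it defines the training labels.
Overlapping rectangles (impossible in the simulator, possible in foreign
layout files) resolve to the first element in snapshot order, with one
warning per stream.

## Featurization

Per-category feature counts are a hard contract, asserted on every schema
build: 35 per lab and vital sign, 31 per ventilator setting, 9 per
medication, 4 per culture and per procedure, 2 per intake/output variable,
1 per atemporal variable. Only five members of the 35 are named in the
source design (first, most recent, highest, lowest, last-two difference);
the remaining 30 are frozen here as a canonical list over the families
count, recency, extreme values and their times, central tendency,
dispersion, range, slopes (whole stay and last 24 h), last-24 h
aggregates, mean-crossing statistics, and the ever-measured flag. The
ventilator list drops the four members that are ill-defined for partly
categorical settings (the two successive-difference statistics and both
slopes). The last-two difference is most-recent minus previous. Features
undefined for short series (standard deviation of one point, last-two
difference of one point, last-24 h aggregates of an empty window) are
missing, not zero. A variable absent from a case fills its group with
missing markers except the ever-measured/ever-given/ever-recorded flag,
which is 0: absence of data is itself the answer to that feature's
question, and this is what lets duplicate ever-measured columns of
co-ordered lab panels be merged rather than dropped as constants.

Preprocessing order is fixed and idempotent stage by stage: constant
columns out, duplicate columns merged (first in schema order survives),
then imputation twice — median/mode (mode ties toward the smallest code)
and regression (per incomplete column, linear or logistic on all other
columns median-pre-filled; degenerate fits fall back to median/mode, with
a log). Observed cells are never altered. The fitted fills and regression
coefficients are retained so evaluation cases are imputed under the
training distribution rather than their own.

## Model selection

Targets are eligible with **strictly more than 3** positive labels among
non-absent cases. Screening considers each predictor variable's group in
isolation: 5-fold cross-validated scores from a 100-tree random forest,
pooled out-of-fold AUROC, kept iff **strictly above 0.55**. The screening
learner is a configurable choice (the source design does not state one); a
tree ensemble is the default because it handles mixed feature types
without scaling. Candidate selection then cross-validates six
configurations — {median, regression} × {L2 logistic (lambda = 1/n),
RBF-SVM (cost 1), random forest (500 trees)} — with one shared stratified
fold assignment so candidates are compared on identical splits; the winner
maximizes mean per-fold AUROC, ties broken median-before-regression,
linear/SVM/forest. Hyperparameters are fixed defaults; there is no inner
tuning loop. Two numerical points deserve note:

* **Screening folds are decoupled from candidate folds.** Screening on the
  very folds used for candidate CV inflates the CV estimates of flexible
  candidates (features were chosen on those splits) and distorts
  selection; with a separate screening fold assignment, parameter-recovery
  experiments at n = 500 recover held-out AUROC within ~0.05 of the
  generative ceiling for most targets, against ~0.10 without.
* **Score orientation and scale.** All scorers return higher = more
  relevant in [0, 1]; SVM decision values are oriented empirically on the
  training data and mapped through the logistic function. AUROC is
  rank-based, so any monotone mapping is equivalent; the logistic map is
  used instead of a within-batch rank transform so that single-case
  predictions are well defined.

When no group survives screening in the winning variant, the model is an
intercept-only scorer at the training prevalence — every target pair must
produce a model for the paired evaluation to stay balanced. Stratified
folds shrink (with a message) when a class has fewer members than folds.

## Paired evaluation

Manual selection is always the evaluation gold standard; gaze labels are
never evaluation truth. Per target, cases where the item is absent are
excluded; AUROC uses the rank formulation with ties counted half, and is
undefined (target dropped, logged) when evaluation labels are single-class.
The paired bootstrap (default B = 2000, percentile intervals, α = 0.05)
resamples evaluation cases, applying the same resample to both models;
single-class resamples are redrawn and counted; B < 100 is refused as
unstable. The difference interval is the percentile interval of the
per-resample paired AUROC difference (manual − gaze) — one of two readings
of "the CI of the average difference"; the per-resample reading is
implemented because it preserves pairing resample by resample. A pair is
significant when that interval excludes zero; per-pair tests are
deliberately uncorrected for multiplicity, matching the comparative design.
Across targets, the paired Wilcoxon signed-rank test (via `wilcox.test`,
the same engine the original analysis used) drops zero differences, uses
mid-ranks for ties, and switches from the exact null to a tie-corrected
normal approximation per that function's standard rules; the all-zero
degenerate case reports p = 1 with a flag instead of erroring. Report rows
sort by manual AUROC, descending.

## Reproducibility and problem sizes

A single global seed spawns per-stage substreams through a fixed affine
map, so stages can rerun independently yet deterministically; identical
configurations reproduce byte-identical cohorts, sessions, and stage
outputs (manifests record config hash and checksums, and deliberately no
timestamps). Problem sizes used by the shipped checks, chosen so the whole
suite runs in minutes on one CPU: module tests use 1–3 vitals/labs-scale
inventories with 8–150 cases; the parameter-recovery suite uses n = 500
training and 500 evaluation cases over a 10-target inventory restricted to
categories whose feature groups express all three latent covariates
(vitals, ventilator, labs, medications — intake/output's two features and
the event categories' four cannot encode "latest value abnormal", so the
generative ceiling does not apply to them); the equivalence property uses
100 replicates of 20 targets × 100 cases simulated at the score level;
bootstrap coverage uses 200 replicates at n = 100 against a binormal
score model whose population AUROC is exactly 0.85. The acceptance script
runs the full study at the design's accounting scale (178 training
sessions, 18 × 4 evaluation sessions) over an 11-target demonstration
inventory.

## Known limitations

Real dwell-time distributions are not described in the source material;
the lognormal two-mode model is a modeling choice, and the 60 ms/1200 ms
medians set a deliberately strong separation. Manual flip noise is
symmetric, which favors the equivalence finding; asymmetric noise (e.g.,
reviewers under-selecting) is expressible via the config but not studied
here. The printed full-inventory feature total of the source design is not
reproducible from its own per-category counts and is treated as
bookkeeping, not a contract. Regression imputation fits each incomplete
column once against median-pre-filled predictors — single-pass, not
iterated/chained. No per-reviewer effects, no free-text features, no
calibration assessment (AUROC only), and no correction for multiple
per-pair comparisons.
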