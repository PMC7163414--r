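# End-to-end orchestration of the comparative study:
# simulate -> QC/label -> featurize -> train (both label sources) ->
# paired evaluation, with a single global seed spawning per-stage
# substreams, plus a file-based stage runner with reproducibility manifests.

#' Study-level run configuration
#'
#' Collects every numeric constant of the study in one place: the dwell
#' threshold (250 ms), the screening AUROC cut (0.55), the minimum positive
#' count (>3), the QC valid-gaze fraction, CV and bootstrap settings, and
#' the two cohort generators.
#'
#' @param training A [sim_config()] for the training cohort (one review
#'   session per case).
#' @param evaluation A [sim_config()] for the evaluation cohort; evaluation
#'   sessions never use gaze (manual selection is the gold standard), so its
#'   `p_gaze_incomplete` is forced to 0.
#' @param n_reviewers Reviewers per evaluation case (each contributes one
#'   session).
#' @param dwell_threshold_ms Gaze-label dwell threshold.
#' @param screen_threshold Feature-group screening AUROC cut (strict).
#' @param min_positives Target eligibility cut (strictly more than this many
#'   positives).
#' @param min_valid_fraction Session QC: minimum fraction of valid gaze
#'   samples.
#' @param max_gap_ms Dwell accumulation cap per sample.
#' @param k Cross-validation folds.
#' @param B,alpha Bootstrap resamples and two-sided miscoverage.
#' @param seed Global seed; all per-stage seeds are derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(training = sim_config(n_cases = 178L),
                       evaluation = sim_config(n_cases = 18L),
                       n_reviewers = 4L,
                       dwell_threshold_ms = 250,
                       screen_threshold = 0.55,
                       min_positives = 3L,
                       min_valid_fraction = 0.5,
                       max_gap_ms = 100,
                       k = 5L, B = 2000L, alpha = 0.05,
                       seed = 1L) {
  stopifnot(inherits(training, "sim_config"), inherits(evaluation, "sim_config"))
  assert_count(n_reviewers, "n_reviewers", min = 1L)
  assert_pos(dwell_threshold_ms, "dwell_threshold_ms")
  assert_count(min_positives, "min_positives")
  assert_count(seed, "seed")
  evaluation$p_gaze_incomplete <- 0
  structure(list(training = training, evaluation = evaluation,
                 n_reviewers = as.integer(n_reviewers),
                 dwell_threshold_ms = dwell_threshold_ms,
                 screen_threshold = screen_threshold,
                 min_positives = as.integer(min_positives),
                 min_valid_fraction = min_valid_fraction,
                 max_gap_ms = max_gap_ms,
                 k = as.integer(k), B = as.integer(B), alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Study run configuration\n")
  cat(sprintf("  training: %d cases; evaluation: %d cases x %d reviewers\n",
              x$training$n_cases, x$evaluation$n_cases, x$n_reviewers))
  cat(sprintf("  thresholds: dwell %g ms, screening AUROC > %g, positives > %d, QC valid fraction >= %g\n",
              x$dwell_threshold_ms, x$screen_threshold, x$min_positives,
              x$min_valid_fraction))
  cat(sprintf("  CV k=%d; bootstrap B=%d, alpha=%g; global seed %d\n",
              x$k, x$B, x$alpha, x$seed))
  invisible(x)
}

# simulate one cohort's review sessions; returns list of review_session
simulate_sessions <- function(cohort, config, n_reviewers = 1L, seed_base = 0L) {
  sessions <- list()
  for (i in seq_along(cohort$cases)) {
    case <- cohort$cases[[i]]
    rel <- true_relevance(case, cohort$model)
    for (r in seq_len(n_reviewers)) {
      sid <- if (n_reviewers == 1L) case$case_id else
        sprintf("%s_r%d", case$case_id, r)
      sessions[[sid]] <- simulate_session(
        case, rel, config, seed = derive_seed(seed_base, i * 101L + r))
      sessions[[sid]]$session_id <- sid
    }
  }
  sessions
}

# labels for the sessions that pass QC; returns list(labels, qc, kept)
label_sessions <- function(sessions, rc, universe, source) {
  qc <- lapply(sessions, qc_session, min_valid_fraction = rc$min_valid_fraction)
  kept <- names(sessions)[vapply(qc, `[[`, TRUE, "valid")]
  labels <- lapply(sessions[kept], function(s) {
    if (source == "gaze") {
      dw <- compute_dwell(s$gaze, s$layout, max_gap_ms = rc$max_gap_ms)
      derive_gaze_labels(dw, s$present_items, rc$dwell_threshold_ms,
                         universe = universe)
    } else {
      derive_manual_labels(s$manual_selections, s$present_items,
                           universe = universe)
    }
  })
  list(labels = labels, qc = qc, kept = kept)
}

#' Run the full comparative study in memory
#'
#' Simulates a training cohort with one review session per case and an
#' evaluation cohort reviewed by several physicians; discards sessions that
#' fail quality control; derives gaze and manual label sets; builds and
#' preprocesses the feature matrices (both imputation variants); trains a
#' relevance model per eligible target for each label source; and evaluates
#' every target that has models from both sources on the evaluation
#' sessions, with manual selection as the gold standard and the absent rule
#' applied per target.
#'
#' @param rc A [run_config()].
#' @return Object of class `relevance_study`: accounting counts, per-source
#'   target tables and fitted models, and the `comparison_report`.
#' @export
run_study <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  tr_cfg <- rc$training
  tr_cfg$seed <- derive_seed(rc$seed, 11L)
  ev_cfg <- rc$evaluation
  ev_cfg$seed <- derive_seed(rc$seed, 12L)

  cohort <- generate_cohort(tr_cfg)
  universe <- cohort$inventory$item_id[cohort$inventory$is_target]
  sessions <- simulate_sessions(cohort, tr_cfg, n_reviewers = 1L,
                                seed_base = derive_seed(rc$seed, 13L))
  gz <- label_sessions(sessions, rc, universe, "gaze")
  mn <- label_sessions(sessions, rc, universe, "manual")
  kept <- gz$kept                      # same QC for both sources
  kept_cases <- cohort$cases[match(kept, vapply(cohort$cases, `[[`, "", "case_id"))]

  raw <- assemble_matrix(kept_cases, cohort$inventory)
  prep <- preprocess_features(raw)

  fits <- list()
  targets <- list()
  for (source in c("manual", "gaze")) {
    labels <- if (source == "gaze") gz$labels else mn$labels
    lm <- label_matrix(labels)
    spec <- eligible_targets(lm, rc$min_positives)
    spec$source <- source
    targets[[source]] <- spec
    fits[[source]] <- list()
    for (it in spec$item_id[spec$eligible]) {
      rows <- which(lm[, it] != "absent")
      y <- as.integer(lm[rows, it] == "positive")
      fits[[source]][[it]] <- relevance_fit(
        subset_rows(prep$median, rows), subset_rows(prep$regression, rows),
        y, target = it, source = source, k = rc$k,
        seed = derive_seed(rc$seed, 20L + match(source, c("manual", "gaze"))),
        screen_threshold = rc$screen_threshold)
    }
  }
  shared <- intersect(names(fits$manual), names(fits$gaze))

  ev_cohort <- generate_cohort(ev_cfg, model = cohort$model)
  ev_sessions <- simulate_sessions(ev_cohort, ev_cfg,
                                   n_reviewers = rc$n_reviewers,
                                   seed_base = derive_seed(rc$seed, 14L))
  ev <- label_sessions(ev_sessions, rc, universe, "manual")
  ev_lm <- label_matrix(ev$labels)

  ev_raw <- assemble_matrix(ev_cohort$cases, ev_cohort$inventory)
  ev_raw <- subset_features(ev_raw, match(colnames(prep$median),
                                          colnames(ev_raw)))
  ev_case_of <- vapply(ev_sessions[ev$kept], `[[`, "", "case_id")
  ev_rows <- match(ev_case_of, rownames(ev_raw))
  ev_mats <- list(
    median = apply_imputation(subset_rows(ev_raw, ev_rows),
                              attr(prep$median, "imputation")),
    regression = apply_imputation(subset_rows(ev_raw, ev_rows),
                                  attr(prep$regression, "imputation")))

  pairs <- lapply(shared, function(it) {
    sel <- which(ev_lm[, it] != "absent")
    list(target = it,
         scores_manual = predict(fits$manual[[it]],
                                 subset_rows(ev_mats[[fits$manual[[it]]$winner$imputation]], sel)),
         scores_gaze = predict(fits$gaze[[it]],
                               subset_rows(ev_mats[[fits$gaze[[it]]$winner$imputation]], sel)),
         labels = as.integer(ev_lm[sel, it] == "positive"))
  })
  report <- build_report(pairs, B = rc$B, alpha = rc$alpha,
                         seed = derive_seed(rc$seed, 30L))

  structure(list(
    config = rc,
    n_training_sessions = length(sessions),
    n_training_flagged = length(sessions) - length(kept),
    n_training_cases = length(kept),
    n_eval_sessions = length(ev_sessions),
    n_eval_flagged = length(ev_sessions) - length(ev$kept),
    n_eval_cases = length(ev$kept),
    targets = targets,
    fits = fits,
    shared_targets = shared,
    report = report
  ), class = "relevance_study")
}

subset_rows <- function(m, rows) {
  structure(unclass(m)[rows, , drop = FALSE],
            schema = attr(m, "schema"), codebooks = attr(m, "codebooks"),
            imputation = attr(m, "imputation"), class = "feature_matrix")
}

#' @export
print.relevance_study <- function(x, ...) {
  cat("Gaze-vs-manual relevance study\n")
  cat(sprintf("  training: %d sessions, %d QC-discarded, %d cases used\n",
              x$n_training_sessions, x$n_training_flagged, x$n_training_cases))
  cat(sprintf("  evaluation: %d sessions, %d QC-discarded, %d used\n",
              x$n_eval_sessions, x$n_eval_flagged, x$n_eval_cases))
  cat(sprintf("  models trained: %d manual, %d gaze; %d shared pairs evaluated\n",
              length(x$fits$manual), length(x$fits$gaze),
              length(x$shared_targets)))
  print(x$report)
  invisible(x)
}

#' @export
summary.relevance_study <- function(object, ...) {
  print(object)
  cat("\n")
  summary(object$report)
  invisible(object)
}

#' @export
plot.relevance_study <- function(x, ...) plot(x$report, ...)
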