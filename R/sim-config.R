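#' Configuration for the synthetic ICU study generator
#'
#' Bundles every knob of the synthetic cohort and review-session generator.
#' The defaults define the study conditions used throughout the package:
#' a scaled-down ICU variable inventory, 60 Hz gaze sampling, lognormal
#' dwell times whose two modes (1200 ms for relevant items, 60 ms for
#' irrelevant ones, sigma 0.5 on the log scale) sit clearly on either side
#' of the 250 ms labeling threshold, and session-loss probabilities chosen
#' so that roughly a quarter of training sessions fail quality control.
#'
#' @param n_cases Number of patient cases to generate.
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts and sessions.
#' @param variable_counts Named integer vector giving the number of
#'   variables per category. Categories: `vitals`, `ventilator`, `labs`,
#'   `medications`, `procedures`, `cultures`, `intake_output`,
#'   `demographics`, `diagnosis`.
#' @param session_duration Review-session capacity in seconds.
#' @param sample_rate Gaze sampling rate in Hz.
#' @param dwell_lognormal_params Named vector `c(mu_rel, mu_irr, sigma)`:
#'   medians (ms) of the lognormal intended-dwell distributions for relevant
#'   and irrelevant items, and the shared log-scale standard deviation.
#' @param manual_flip_noise Probability that a manual checkbox selection
#'   disagrees with the underlying relevance draw.
#' @param missing_rate Probability that a (non-atemporal) variable has no
#'   data in a given case.
#' @param p_gaze_incomplete Probability a session's gaze capture is
#'   incomplete (most samples invalid), as when a reviewer's head leaves the
#'   tracker range.
#' @param p_selection_skipped Probability the checkbox selection task is
#'   skipped in a session.
#' @param prediction_time_min Prediction time in minutes after admission.
#' @param p_recent Probability a present variable was measured within the
#'   24 h before prediction time.
#' @param p_abnormal Probability the latest value of a present variable is
#'   outside its reference range.
#' @param relevance_coef Named vector `c(intercept, recent, abnormal,
#'   diagnosis)` of latent logistic-model coefficients linking case
#'   summaries to item relevance. The defaults give a generative
#'   (Bayes-optimal) AUROC of about 0.85 at a positive rate of about 0.40.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 20L,
                       seed = 1L,
                       variable_counts = c(vitals = 14L, ventilator = 9L,
                                           labs = 20L, medications = 30L,
                                           procedures = 10L, cultures = 5L,
                                           intake_output = 7L,
                                           demographics = 6L, diagnosis = 1L),
                       session_duration = 180,
                       sample_rate = 60,
                       dwell_lognormal_params = c(mu_rel = 1200, mu_irr = 60,
                                                  sigma = 0.5),
                       manual_flip_noise = 0.05,
                       missing_rate = 0.2,
                       p_gaze_incomplete = 0.2,
                       p_selection_skipped = 0.06,
                       prediction_time_min = 2880,
                       p_recent = 0.7,
                       p_abnormal = 0.35,
                       relevance_coef = c(intercept = -4.40, recent = 2.52,
                                          abnormal = 2.49, diagnosis = 2.14)) {
  assert_count(n_cases, "n_cases", min = 0L)
  assert_count(seed, "seed")
  assert_pos(sample_rate, "sample_rate")
  assert_pos(session_duration, "session_duration")
  assert_prob(manual_flip_noise, "manual_flip_noise")
  assert_prob(missing_rate, "missing_rate")
  assert_prob(p_gaze_incomplete, "p_gaze_incomplete")
  assert_prob(p_selection_skipped, "p_selection_skipped")
  assert_prob(p_recent, "p_recent")
  assert_prob(p_abnormal, "p_abnormal")
  if (prediction_time_min <= 1440) {
    stopf("'prediction_time_min' must exceed 1440 (one day of lookback)")
  }

  known <- c("vitals", "ventilator", "labs", "medications", "procedures",
             "cultures", "intake_output", "demographics", "diagnosis")
  if (is.null(names(variable_counts)) ||
      !all(names(variable_counts) %in% known)) {
    stopf("'variable_counts' must be named with categories among: %s",
          paste(known, collapse = ", "))
  }
  counts <- stats::setNames(integer(length(known)), known)
  counts[names(variable_counts)] <- as.integer(variable_counts)
  if (any(counts < 0)) stopf("'variable_counts' must be non-negative")

  d <- dwell_lognormal_params
  if (length(d) != 3L || is.null(names(d)) ||
      !all(c("mu_rel", "mu_irr", "sigma") %in% names(d))) {
    stopf("'dwell_lognormal_params' must be named c(mu_rel, mu_irr, sigma)")
  }
  if (d[["mu_rel"]] <= d[["mu_irr"]]) {
    stopf("'dwell_lognormal_params': mu_rel must exceed mu_irr")
  }
  if (d[["sigma"]] <= 0) stopf("'dwell_lognormal_params': sigma must be > 0")

  rc <- relevance_coef
  if (length(rc) != 4L || is.null(names(rc)) ||
      !all(c("intercept", "recent", "abnormal", "diagnosis") %in% names(rc))) {
    stopf("'relevance_coef' must be named c(intercept, recent, abnormal, diagnosis)")
  }

  structure(list(
    n_cases = as.integer(n_cases),
    seed = as.integer(seed),
    variable_counts = counts,
    session_duration = session_duration,
    sample_rate = sample_rate,
    dwell_lognormal_params = d[c("mu_rel", "mu_irr", "sigma")],
    manual_flip_noise = manual_flip_noise,
    missing_rate = missing_rate,
    p_gaze_incomplete = p_gaze_incomplete,
    p_selection_skipped = p_selection_skipped,
    prediction_time_min = prediction_time_min,
    p_recent = p_recent,
    p_abnormal = p_abnormal,
    relevance_coef = rc[c("intercept", "recent", "abnormal", "diagnosis")]
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ICU study configuration\n")
  cat(sprintf("  cases: %d (seed %d)\n", x$n_cases, x$seed))
  cat(sprintf("  variables: %s\n",
              paste(sprintf("%s=%d", names(x$variable_counts),
                            x$variable_counts), collapse = " ")))
  cat(sprintf("  session: %gs at %g Hz; dwell lognormal mu_rel=%g mu_irr=%g sigma=%g ms\n",
              x$session_duration, x$sample_rate,
              x$dwell_lognormal_params[["mu_rel"]],
              x$dwell_lognormal_params[["mu_irr"]],
              x$dwell_lognormal_params[["sigma"]]))
  cat(sprintf("  noise: manual flips %.2f, missing %.2f, gaze incomplete %.2f, selection skipped %.2f\n",
              x$manual_flip_noise, x$missing_rate,
              x$p_gaze_incomplete, x$p_selection_skipped))
  invisible(x)
}
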