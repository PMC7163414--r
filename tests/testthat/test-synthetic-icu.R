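# Synthetic cohort and review-session generator.

test_that("invalid configuration fields are rejected with the field name", {
  expect_error(sim_config(manual_flip_noise = 1.5), "manual_flip_noise")
  expect_error(sim_config(missing_rate = -0.1), "missing_rate")
  expect_error(sim_config(sample_rate = 0), "sample_rate")
  expect_error(sim_config(n_cases = -1), "n_cases")
  expect_error(sim_config(dwell_lognormal_params =
                            c(mu_rel = 60, mu_irr = 1200, sigma = 0.5)),
               "mu_rel")
  expect_error(sim_config(variable_counts = c(bogus = 3L)), "variable_counts")
})

test_that("an empty cohort is valid and carries a usable relevance model", {
  co <- generate_cohort(sim_config(n_cases = 0L, variable_counts = tiny_counts))
  expect_length(co$cases, 0)
  expect_s3_class(co$model, "relevance_model")
  expect_gt(nrow(co$model$coef), 0)
})

test_that("cohort generation hits the requested size with balanced diagnoses", {
  co <- generate_cohort(sim_config(n_cases = 134L, seed = 7L))
  expect_length(co$cases, 134)
  dg <- table(vapply(co$cases, `[[`, "", "diagnosis"))
  expect_lte(abs(dg[["AKF"]] - dg[["ARF"]]), 1)
})

test_that("cohorts are bitwise reproducible under the seed", {
  cfg7 <- sim_config(n_cases = 12L, seed = 7L, variable_counts = tiny_counts)
  cfg8 <- sim_config(n_cases = 12L, seed = 8L, variable_counts = tiny_counts)
  expect_identical(generate_cohort(cfg7), generate_cohort(cfg7))
  expect_false(identical(generate_cohort(cfg7)$cases,
                         generate_cohort(cfg8)$cases))
})

test_that("variables are present at roughly 1 - missing_rate", {
  cfg <- sim_config(n_cases = 150L, seed = 3L, missing_rate = 0.3,
                    variable_counts = tiny_counts)
  co <- generate_cohort(cfg)
  n_target <- sum(co$inventory$is_target)
  present <- vapply(co$cases, function(cs) length(cs$series), 0)
  expect_equal(mean(present) / n_target, 0.7, tolerance = 0.08)
})

test_that("case series respect the timestamp and presence invariants", {
  co <- generate_cohort(sim_config(n_cases = 25L, seed = 11L,
                                   variable_counts = tiny_counts))
  for (cs in co$cases) {
    for (s in cs$series) {
      expect_gt(nrow(s), 0)          # absent variables have no entry at all
      expect_false(is.unsorted(s$t))
      expect_true(all(s$t >= cs$admission_time & s$t <= cs$prediction_time))
    }
  }
})

test_that("true relevance follows the logistic model exactly", {
  cfg <- sim_config(n_cases = 5L, seed = 2L, variable_counts = tiny_counts)
  co <- generate_cohort(cfg)
  case <- co$cases[[1]]

  # all-zero coefficients: every present item sits at logistic(0) = 0.5
  m0 <- co$model
  m0$coef[] <- 0
  p0 <- true_relevance(case, m0)
  expect_true(all(p0[names(case$series)] == 0.5))
  expect_true(all(is.na(p0[setdiff(names(p0), names(case$series))])))

  # strongly negative intercept drives probabilities toward 0
  mneg <- co$model
  mneg$coef[, "intercept"] <- -30
  expect_lt(max(true_relevance(case, mneg), na.rm = TRUE), 1e-6)

  # hand-computed logistic for one item from its recoverable summaries
  it <- names(case$series)[1]
  z <- case_item_summaries(case, co$inventory, it)
  b <- co$model$coef[it, ]
  by_hand <- plogis(b[["intercept"]] + b[["recent"]] * z[["recent"]] +
                    b[["abnormal"]] * z[["abnormal"]] +
                    b[["diagnosis"]] * z[["diagnosis"]])
  expect_equal(unname(true_relevance(case, co$model)[it]), unname(by_hand))
})

test_that("a case with variables outside the model schema is rejected", {
  co <- generate_cohort(sim_config(n_cases = 2L, variable_counts = tiny_counts))
  case <- co$cases[[1]]
  case$series[["rogue_item"]] <- data.frame(t = 1, value = 1)
  expect_error(true_relevance(case, co$model), "rogue_item")
})

test_that("sessions are reproducible and respect dwell conservation", {
  cfg <- sim_config(n_cases = 3L, seed = 5L, variable_counts = tiny_counts)
  co <- generate_cohort(cfg)
  rel <- true_relevance(co$cases[[1]], co$model)
  s1 <- simulate_session(co$cases[[1]], rel, cfg, seed = 9L)
  s2 <- simulate_session(co$cases[[1]], rel, cfg, seed = 9L)
  s3 <- simulate_session(co$cases[[1]], rel, cfg, seed = 10L)
  expect_identical(s1, s2)
  expect_false(identical(s1$gaze, s3$gaze))
  expect_lte(sum(s1$intended$dwell_ms), cfg$session_duration * 1000)
  expect_true(all(s1$manual_selections %in% s1$present_items))
})

test_that("a too-short session is reported as infeasible", {
  cfg <- sim_config(n_cases = 1L, seed = 5L, variable_counts = tiny_counts,
                    session_duration = 0.5)
  co <- generate_cohort(cfg)
  rel <- true_relevance(co$cases[[1]], co$model)
  expect_error(simulate_session(co$cases[[1]], rel, cfg, seed = 1L),
               "infeasible")
})

test_that("noise-free manual selections equal the relevant-item set", {
  cfg <- sim_config(n_cases = 1L, seed = 4L, variable_counts = tiny_counts,
                    manual_flip_noise = 0, p_selection_skipped = 0,
                    p_gaze_incomplete = 0)
  co <- generate_cohort(cfg)
  rel <- true_relevance(co$cases[[1]], co$model)
  rel[!is.na(rel)] <- rep_len(c(0, 1), sum(!is.na(rel)))  # degenerate probs
  s <- simulate_session(co$cases[[1]], rel, cfg, seed = 2L)
  expect_setequal(s$manual_selections, names(rel)[!is.na(rel) & rel == 1])
})

test_that("the gaze pipeline recovers intended dwells within one sample period", {
  cfg <- sim_config(n_cases = 2L, seed = 6L, variable_counts = tiny_counts,
                    p_gaze_incomplete = 0, p_selection_skipped = 0)
  co <- generate_cohort(cfg)
  period <- 1000 / cfg$sample_rate
  for (case in co$cases) {
    s <- simulate_session(case, true_relevance(case, co$model), cfg, seed = 3L)
    dw <- compute_dwell(s$gaze, s$layout)
    err <- abs(dw[s$intended$item_id] - s$intended$dwell_ms)
    expect_lt(max(err), period)
  }
})

test_that("widening the dwell-mode separation strengthens the gaze label signal", {
  agreement <- function(mu_rel) {
    cfg <- sim_config(n_cases = 4L, seed = 8L, variable_counts = tiny_counts,
                      dwell_lognormal_params = c(mu_rel = mu_rel, mu_irr = 150,
                                                 sigma = 0.5),
                      p_gaze_incomplete = 0, p_selection_skipped = 0)
    co <- generate_cohort(cfg)
    agr <- 0; tot <- 0
    for (i in seq_along(co$cases)) {
      for (sd in 1:4) {
        s <- simulate_session(co$cases[[i]],
                              true_relevance(co$cases[[i]], co$model),
                              cfg, seed = 100L * i + sd)
        dw <- compute_dwell(s$gaze, s$layout)
        lab <- derive_gaze_labels(dw, s$present_items)
        agr <- agr + sum((lab[s$intended$item_id] == "positive") ==
                           s$intended$relevant)
        tot <- tot + nrow(s$intended)
      }
    }
    agr / tot
  }
  a <- vapply(c(160, 400, 1600), agreement, 0)
  expect_true(all(diff(a) > 0))
})
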