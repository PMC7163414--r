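# File-based stage runner. Each stage reads upstream artifacts from the
# output directory, writes its outputs, and records a manifest (config
# hash, seed, input checksums, output checksums and row counts). Stages are
# idempotent: rerunning with an unchanged configuration reproduces
# byte-identical outputs.

STAGES <- c("simulate", "label", "featurize", "train", "evaluate", "run_all")

#' Run one pipeline stage against an output directory
#'
#' Stages: `simulate` (cohorts, review sessions, selection records),
#' `label` (QC, dwell tables, gaze and manual label sets), `featurize`
#' (feature matrices, both imputation variants, training and evaluation),
#' `train` (per-target models for both label sources, with a training
#' manifest), `evaluate` (paired scoring and the comparison report), or
#' `run_all`. Missing upstream artifacts raise an error naming the missing
#' file.
#'
#' @param stage One of the stage names above.
#' @param rc A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest (invisibly), or for `run_all` the final
#'   `relevance_study`-style result list.
#' @export
run_stage <- function(stage, rc, outdir) {
  stage <- match.arg(stage, STAGES)
  stopifnot(inherits(rc, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "run_all") {
    for (s in c("simulate", "label", "featurize", "train", "evaluate")) {
      run_stage(s, rc, outdir)
    }
    return(invisible(read_stage_manifest(outdir, "evaluate")))
  }
  switch(stage,
         simulate = stage_simulate(rc, outdir),
         label = stage_label(rc, outdir),
         featurize = stage_featurize(rc, outdir),
         train = stage_train(rc, outdir),
         evaluate = stage_evaluate(rc, outdir))
}

need_upstream <- function(path) {
  if (!file.exists(path)) {
    stopf("missing upstream artifact '%s'; run the earlier stage first", path)
  }
  path
}

write_stage_manifest <- function(outdir, stage, rc, inputs, outputs, rows) {
  man <- list(stage = stage,
              config_hash = object_md5(unclass_config(rc)),
              seed = rc$seed,
              inputs = as.list(vapply(inputs, file_md5, "")),
              outputs = as.list(vapply(outputs, file_md5, "")),
              row_counts = as.list(rows))
  names(man$inputs) <- basename(inputs)
  names(man$outputs) <- basename(outputs)
  jsonlite::write_json(man, file.path(outdir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

read_stage_manifest <- function(outdir, stage) {
  jsonlite::read_json(need_upstream(
    file.path(outdir, sprintf("manifest_%s.json", stage))))
}

unclass_config <- function(rc) {
  rc <- unclass(rc)
  rc$training <- as.list(unclass(rc$training))
  rc$evaluation <- as.list(unclass(rc$evaluation))
  rc
}

stage_simulate <- function(rc, outdir) {
  tr_cfg <- rc$training; tr_cfg$seed <- derive_seed(rc$seed, 11L)
  ev_cfg <- rc$evaluation; ev_cfg$seed <- derive_seed(rc$seed, 12L)
  cohort <- generate_cohort(tr_cfg)
  ev_cohort <- generate_cohort(ev_cfg, model = cohort$model)
  sessions <- simulate_sessions(cohort, tr_cfg, 1L, derive_seed(rc$seed, 13L))
  ev_sessions <- simulate_sessions(ev_cohort, ev_cfg, rc$n_reviewers,
                                   derive_seed(rc$seed, 14L))
  for (d in c("cases", "eval_cases", "sessions")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  for (case in cohort$cases) {
    write_case_json(case, file.path(outdir, "cases",
                                    paste0(case$case_id, ".json")))
  }
  for (case in ev_cohort$cases) {
    write_case_json(case, file.path(outdir, "eval_cases",
                                    paste0(case$case_id, ".json")))
  }
  utils::write.csv(cohort$inventory, file.path(outdir, "inventory.csv"),
                   row.names = FALSE)
  write_cohort_manifest(cohort, file.path(outdir, "cohort_manifest.csv"))
  write_cohort_manifest(ev_cohort, file.path(outdir, "eval_cohort_manifest.csv"))
  for (s in sessions) {
    write_gaze_csv(s$gaze, file.path(outdir, "sessions",
                                     paste0(s$session_id, ".gaze.csv")))
    write_layout_jsonl(s$layout, file.path(outdir, "sessions",
                                           paste0(s$session_id, ".layout.jsonl")))
  }
  session_index <- function(ss) data.frame(
    session_id = vapply(ss, `[[`, "", "session_id"),
    case_id = vapply(ss, `[[`, "", "case_id"),
    has_selection_record = vapply(ss, function(s)
      as.integer(!is.null(s$manual_selections)), 0L))
  utils::write.csv(session_index(sessions),
                   file.path(outdir, "sessions.csv"), row.names = FALSE)
  utils::write.csv(session_index(ev_sessions),
                   file.path(outdir, "eval_sessions.csv"), row.names = FALSE)
  sel_of <- function(ss) {
    keep <- Filter(function(s) !is.null(s$manual_selections), ss)
    stats::setNames(lapply(keep, `[[`, "manual_selections"),
                    vapply(keep, `[[`, "", "session_id"))
  }
  write_selections_csv(sel_of(sessions), file.path(outdir, "selections.csv"))
  write_selections_csv(sel_of(ev_sessions),
                       file.path(outdir, "eval_selections.csv"))
  # present items per evaluation session (gaze streams are not retained for
  # evaluation sessions: manual selection is the evaluation gold standard)
  pres <- do.call(rbind, lapply(ev_sessions, function(s)
    data.frame(session_id = s$session_id, item_id = s$present_items)))
  utils::write.csv(pres, file.path(outdir, "eval_present_items.csv"),
                   row.names = FALSE)
  outs <- file.path(outdir, c("inventory.csv", "cohort_manifest.csv",
                              "eval_cohort_manifest.csv", "sessions.csv",
                              "eval_sessions.csv", "selections.csv",
                              "eval_selections.csv", "eval_present_items.csv"))
  write_stage_manifest(outdir, "simulate", rc, character(0), outs,
                       list(training_sessions = length(sessions),
                            evaluation_sessions = length(ev_sessions)))
}

stage_label <- function(rc, outdir) {
  idx <- utils::read.csv(need_upstream(file.path(outdir, "sessions.csv")))
  inv <- utils::read.csv(need_upstream(file.path(outdir, "inventory.csv")))
  universe <- inv$item_id[inv$is_target == 1 | inv$is_target == TRUE]
  sels <- read_selections_csv(need_upstream(file.path(outdir, "selections.csv")))
  qc_rows <- list(); dwells <- list()
  labels_g <- list(); labels_m <- list()
  for (i in seq_len(nrow(idx))) {
    sid <- idx$session_id[i]
    gaze <- read_gaze_csv(need_upstream(
      file.path(outdir, "sessions", paste0(sid, ".gaze.csv"))))
    layout <- read_layout_jsonl(need_upstream(
      file.path(outdir, "sessions", paste0(sid, ".layout.jsonl"))))
    present <- unique(unlist(lapply(layout, function(s) s$elements$item_id)))
    session <- list(gaze = gaze,
                    manual_selections = if (idx$has_selection_record[i] == 1L)
                      as.character(sels[[sid]] %||% character(0)) else NULL)
    qc <- qc_session(session, rc$min_valid_fraction)
    qc_rows[[sid]] <- data.frame(session_id = sid, valid = qc$valid,
                                 valid_sample_fraction = qc$valid_sample_fraction,
                                 reasons = paste(qc$reasons, collapse = ";"))
    if (!qc$valid) next
    dw <- compute_dwell(gaze, layout, max_gap_ms = rc$max_gap_ms)
    dwells[[sid]] <- dw
    labels_g[[sid]] <- derive_gaze_labels(dw, present, rc$dwell_threshold_ms,
                                          universe = universe)
    labels_m[[sid]] <- derive_manual_labels(session$manual_selections, present,
                                            universe = universe)
  }
  utils::write.csv(do.call(rbind, qc_rows), file.path(outdir, "qc.csv"),
                   row.names = FALSE)
  write_dwell_csv(dwells, file.path(outdir, "dwell.csv"))
  write_labels_csv(labels_g, file.path(outdir, "labels_gaze.csv"))
  write_labels_csv(labels_m, file.path(outdir, "labels_manual.csv"))

  # evaluation sessions: manual labels only, skipped sessions dropped
  ev_idx <- utils::read.csv(need_upstream(file.path(outdir, "eval_sessions.csv")))
  ev_sels <- read_selections_csv(need_upstream(
    file.path(outdir, "eval_selections.csv")))
  ev_pres <- utils::read.csv(need_upstream(
    file.path(outdir, "eval_present_items.csv")))
  ev_labels <- list()
  for (i in seq_len(nrow(ev_idx))) {
    if (ev_idx$has_selection_record[i] != 1L) next
    sid <- ev_idx$session_id[i]
    present <- ev_pres$item_id[ev_pres$session_id == sid]
    ev_labels[[sid]] <- derive_manual_labels(
      as.character(ev_sels[[sid]] %||% character(0)), present,
      universe = universe)
  }
  write_labels_csv(ev_labels, file.path(outdir, "eval_labels_manual.csv"))
  ins <- file.path(outdir, c("sessions.csv", "inventory.csv", "selections.csv",
                             "eval_sessions.csv", "eval_selections.csv"))
  outs <- file.path(outdir, c("qc.csv", "dwell.csv", "labels_gaze.csv",
                              "labels_manual.csv", "eval_labels_manual.csv"))
  write_stage_manifest(outdir, "label", rc, ins, outs,
                       list(sessions_kept = length(labels_g),
                            evaluation_sessions_kept = length(ev_labels)))
}

stage_featurize <- function(rc, outdir) {
  inv <- utils::read.csv(need_upstream(file.path(outdir, "inventory.csv")))
  inv$is_target <- inv$is_target == 1 | inv$is_target == TRUE
  qc <- utils::read.csv(need_upstream(file.path(outdir, "qc.csv")))
  kept <- qc$session_id[qc$valid == 1 | qc$valid == TRUE]
  cases <- lapply(kept, function(cid) read_case_json(need_upstream(
    file.path(outdir, "cases", paste0(cid, ".json")))))
  raw <- assemble_matrix(cases, inv)
  prep <- preprocess_features(raw)
  write_matrix_csv(prep$median, file.path(outdir, "train_median.csv"))
  write_matrix_csv(prep$regression, file.path(outdir, "train_regression.csv"))

  ev_labels <- read_labels_csv(need_upstream(
    file.path(outdir, "eval_labels_manual.csv")))
  ev_idx <- utils::read.csv(need_upstream(file.path(outdir, "eval_sessions.csv")))
  ev_kept <- intersect(ev_idx$session_id, names(ev_labels))
  ev_cases <- lapply(unique(ev_idx$case_id), function(cid) read_case_json(
    need_upstream(file.path(outdir, "eval_cases", paste0(cid, ".json")))))
  ev_raw <- assemble_matrix(ev_cases, inv)
  ev_raw <- subset_features(ev_raw, match(colnames(prep$median),
                                          colnames(ev_raw)))
  rows <- match(ev_idx$case_id[match(ev_kept, ev_idx$session_id)],
                rownames(ev_raw))
  for (v in c("median", "regression")) {
    m <- apply_imputation(subset_rows(ev_raw, rows),
                          attr(prep[[v]], "imputation"))
    rownames(m) <- ev_kept           # one feature row per kept session
    write_matrix_csv(m, file.path(outdir, sprintf("eval_%s.csv", v)))
  }
  ins <- file.path(outdir, c("inventory.csv", "qc.csv",
                             "eval_labels_manual.csv", "eval_sessions.csv"))
  outs <- file.path(outdir, c("train_median.csv", "train_regression.csv",
                              "eval_median.csv", "eval_regression.csv"))
  write_stage_manifest(outdir, "featurize", rc, ins, outs,
                       list(training_rows = nrow(prep$median),
                            evaluation_rows = length(rows),
                            features = ncol(prep$median)))
}

stage_train <- function(rc, outdir) {
  med <- read_matrix_csv(need_upstream(file.path(outdir, "train_median.csv")))
  reg <- read_matrix_csv(need_upstream(file.path(outdir, "train_regression.csv")))
  dir.create(file.path(outdir, "models"), showWarnings = FALSE)
  manifest_rows <- list()
  for (source in c("manual", "gaze")) {
    labels <- read_labels_csv(need_upstream(
      file.path(outdir, sprintf("labels_%s.csv", source))))
    lm <- label_matrix(labels)
    lm <- lm[rownames(med), , drop = FALSE]
    spec <- eligible_targets(structure(lm, source = source), rc$min_positives)
    for (it in spec$item_id[spec$eligible]) {
      rows <- which(lm[, it] != "absent")
      y <- as.integer(lm[rows, it] == "positive")
      fit <- relevance_fit(subset_rows(med, rows), subset_rows(reg, rows), y,
                           target = it, source = source, k = rc$k,
                           seed = derive_seed(rc$seed,
                                              20L + match(source,
                                                          c("manual", "gaze"))),
                           screen_threshold = rc$screen_threshold)
      stem <- file.path(outdir, "models", sprintf("%s_%s", source, it))
      saveRDS(fit, paste0(stem, ".rds"))
      jsonlite::write_json(
        list(target = it, source = source,
             winner = as.list(fit$winner), cv_auroc = fit$cv_auroc,
             candidates = fit$candidates,
             kept_groups = fit$screened_groups, fallback = fit$fallback,
             n_positive = fit$n_positive, seed = fit$seed),
        paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
      manifest_rows[[paste(source, it)]] <- data.frame(
        source = source, target = it, imputation = fit$winner$imputation,
        classifier = fit$winner$classifier, cv_auroc = fit$cv_auroc,
        n_positive = fit$n_positive, fallback = fit$fallback)
    }
  }
  tm <- do.call(rbind, manifest_rows)
  rownames(tm) <- NULL
  utils::write.csv(tm, file.path(outdir, "training_manifest.csv"),
                   row.names = FALSE)
  ins <- file.path(outdir, c("train_median.csv", "train_regression.csv",
                             "labels_manual.csv", "labels_gaze.csv"))
  outs <- file.path(outdir, "training_manifest.csv")
  write_stage_manifest(outdir, "train", rc, ins, outs,
                       list(models_manual = sum(tm$source == "manual"),
                            models_gaze = sum(tm$source == "gaze")))
}

stage_evaluate <- function(rc, outdir) {
  tm <- utils::read.csv(need_upstream(file.path(outdir, "training_manifest.csv")))
  ev_labels <- read_labels_csv(need_upstream(
    file.path(outdir, "eval_labels_manual.csv")))
  ev_lm <- label_matrix(ev_labels)
  mats <- list(
    median = read_matrix_csv(need_upstream(file.path(outdir, "eval_median.csv"))),
    regression = read_matrix_csv(need_upstream(
      file.path(outdir, "eval_regression.csv"))))
  ev_lm <- ev_lm[rownames(mats$median), , drop = FALSE]
  shared <- intersect(tm$target[tm$source == "manual"],
                      tm$target[tm$source == "gaze"])
  pairs <- lapply(shared, function(it) {
    sel <- which(ev_lm[, it] != "absent")
    score <- function(source) {
      fit <- readRDS(need_upstream(
        file.path(outdir, "models", sprintf("%s_%s.rds", source, it))))
      predict(fit, subset_rows(mats[[fit$winner$imputation]], sel))
    }
    list(target = it, scores_manual = score("manual"),
         scores_gaze = score("gaze"),
         labels = as.integer(ev_lm[sel, it] == "positive"))
  })
  report <- build_report(pairs, B = rc$B, alpha = rc$alpha,
                         seed = derive_seed(rc$seed, 30L))
  write_report(report, file.path(outdir, "report"))
  ins <- file.path(outdir, c("training_manifest.csv", "eval_labels_manual.csv",
                             "eval_median.csv", "eval_regression.csv"))
  outs <- file.path(outdir, c("report.csv", "report.json",
                              "report_scatter.csv"))
  write_stage_manifest(outdir, "evaluate", rc, ins, outs,
                       list(pairs = nrow(report$table)))
}
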