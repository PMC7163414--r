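# Plain-text external interfaces: cases as JSON, gaze streams as CSV,
# layout streams as JSON Lines, labels/matrices/reports as CSV with JSON
# sidecars. Readers and writers round-trip.

#' Write / read one patient case as JSON
#'
#' @param case A patient case (element of `cohort$cases`).
#' @param path Output file.
#' @export
write_case_json <- function(case, path) {
  doc <- list(case_id = case$case_id, diagnosis = case$diagnosis,
              demographics = case$demographics,
              admission_time = case$admission_time,
              prediction_time = case$prediction_time,
              series = lapply(case$series, function(s) {
                list(t = s$t, value = s$value)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_case_json
#' @export
read_case_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  series <- lapply(doc$series, function(s) {
    data.frame(t = as.numeric(s$t), value = as.numeric(s$value))
  })
  list(case_id = doc$case_id, diagnosis = doc$diagnosis,
       demographics = as.list(doc$demographics),
       series = series,
       admission_time = doc$admission_time,
       prediction_time = doc$prediction_time)
}

#' Write the cohort manifest CSV
#'
#' One row per case: `case_id`, `diagnosis`, `prediction_time`.
#' @param cohort An `icu_cohort`.
#' @param path Output file.
#' @export
write_cohort_manifest <- function(cohort, path) {
  df <- data.frame(
    case_id = vapply(cohort$cases, `[[`, "", "case_id"),
    diagnosis = vapply(cohort$cases, `[[`, "", "diagnosis"),
    prediction_time = vapply(cohort$cases, `[[`, 0, "prediction_time"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a gaze stream CSV
#'
#' Header `timestamp_ms,x_px,y_px,valid` with `valid` in `{0,1}`.
#' @param gaze Data frame with those columns.
#' @param path File path.
#' @export
write_gaze_csv <- function(gaze, path) {
  utils::write.csv(gaze[, c("timestamp_ms", "x_px", "y_px", "valid")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  g <- utils::read.csv(path)
  stopifnot(identical(names(g), c("timestamp_ms", "x_px", "y_px", "valid")))
  g
}

#' Write / read a layout stream as JSON Lines
#'
#' One line per snapshot:
#' `{"timestamp_ms": t, "elements": [{"item_id", "x0","y0","x1","y1"}, ...]}`
#' in pixels.
#' @param layout List of snapshots (see [simulate_session()]).
#' @param path File path.
#' @export
write_layout_jsonl <- function(layout, path) {
  lines <- vapply(layout, function(s) {
    jsonlite::toJSON(list(timestamp_ms = s$timestamp_ms,
                          elements = s$elements),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_layout_jsonl
#' @export
read_layout_jsonl <- function(path) {
  lapply(readLines(path), function(ln) {
    doc <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    list(timestamp_ms = doc$timestamp_ms,
         elements = as.data.frame(doc$elements))
  })
}

#' Write / read manual selections CSV (`case_id,item_id`)
#'
#' @param selections Named list: per case, a character vector of selected
#'   item ids (omit cases whose selection task was skipped).
#' @param path File path.
#' @export
write_selections_csv <- function(selections, path) {
  rows <- do.call(rbind, c(list(data.frame(case_id = character(0),
                                           item_id = character(0))),
                           lapply(names(selections), function(cid) {
    if (length(selections[[cid]]) == 0L) return(NULL)
    data.frame(case_id = cid, item_id = selections[[cid]],
               stringsAsFactors = FALSE)
  })))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selections_csv
#' @export
read_selections_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  split(df$item_id, df$case_id)
}

#' Write a dwell table CSV (`case_id,item_id,dwell_ms`)
#'
#' @param dwells Named list of `dwell_table`s keyed by case id.
#' @param path File path.
#' @export
write_dwell_csv <- function(dwells, path) {
  rows <- do.call(rbind, lapply(names(dwells), function(cid) {
    d <- dwells[[cid]]
    data.frame(case_id = cid, item_id = names(d),
               dwell_ms = as.numeric(d), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labels CSV (`case_id,item_id,label,source`)
#'
#' @param labels Named list of `label_set`s keyed by case id.
#' @param path File path.
#' @export
write_labels_csv <- function(labels, path) {
  rows <- do.call(rbind, lapply(names(labels), function(cid) {
    l <- labels[[cid]]
    data.frame(case_id = cid, item_id = names(l), label = as.character(l),
               source = attr(l, "source") %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  out <- lapply(split(df, df$case_id), function(d) {
    structure(stats::setNames(d$label, d$item_id), class = "label_set",
              source = d$source[1L])
  })
  out[unique(df$case_id)]
}

#' Write / read a feature matrix as CSV plus a JSON schema sidecar
#'
#' The CSV holds one row per case (first column `case_id`); missing values
#' are empty fields. The sidecar (`<path>.schema.json`) records the
#' feature-to-variable-group map, categories, types, and codebooks.
#'
#' @param m A `feature_matrix`.
#' @param path CSV path; the sidecar is written next to it.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(case_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(schema = attr(m, "schema"), codebooks = attr(m, "codebooks")),
    paste0(path, ".schema.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".schema.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$case_id
  structure(m, schema = as.data.frame(side$schema),
            codebooks = as.list(side$codebooks), class = "feature_matrix")
}

#' Write a comparison report (CSV table + JSON summary + plot data)
#'
#' `"<stem>.csv"` holds the per-target table, `"<stem>.json"` the Wilcoxon
#' statistic and significance counts, and `"<stem>_scatter.csv"` the
#' scatter-plot data (AUROC pair, CI whiskers, significance flag).
#'
#' @param report A `comparison_report`.
#' @param stem Output path stem.
#' @export
write_report <- function(report, stem) {
  utils::write.csv(report$table, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(wilcoxon_stat = report$wilcoxon$statistic,
         wilcoxon_p = report$wilcoxon$p_value,
         n_pairs = nrow(report$table),
         n_significant_manual = report$n_significant_manual,
         n_significant_gaze = report$n_significant_gaze,
         dropped = report$dropped),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  sc <- report$table[, c("target", "auroc_manual", "ci_manual_lo",
                         "ci_manual_hi", "auroc_gaze", "ci_gaze_lo",
                         "ci_gaze_hi", "significant", "direction")]
  utils::write.csv(sc, paste0(stem, "_scatter.csv"), row.names = FALSE)
  invisible(stem)
}
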