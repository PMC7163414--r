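# Clinical time-series feature construction: a fixed-width grouped feature
# vector per patient case.
#
# Per-category feature counts are a hard contract: 35 for each laboratory
# test and vital sign, 31 for each ventilator setting, 9 per medication,
# 4 per culture and per procedure, 2 per intake/output variable, and 1 per
# atemporal variable. The five named members for numeric series (first,
# most recent, highest, lowest, last-two difference) are fixed; the
# remainder is a frozen canonical list drawn from the families count,
# recency, extremes and their times, central tendency, dispersion, range,
# slopes, last-24 h aggregates, mean-crossing counts, and ever-measured.

# Canonical 35-feature list for numeric series (labs, vitals).
NUMERIC_SERIES_FEATURES <- c(
  "first_value", "last_value", "min_value", "max_value",
  "mean_value", "median_value", "sd_value", "iqr_value", "range_value",
  "diff_last_two", "diff_first_last",
  "mean_abs_successive_diff", "max_abs_successive_diff", "slope_overall",
  "time_since_first", "time_since_last",
  "time_of_min", "time_of_max", "time_since_min", "time_since_max",
  "gap_last_two", "mean_gap",
  "n_measurements", "measurement_rate", "ever_measured",
  "n_last24h", "mean_last24h", "min_last24h", "max_last24h", "sd_last24h",
  "slope_last24h", "measured_last24h",
  "n_crossings_mean", "frac_above_mean", "last_minus_mean")

# Ventilator settings can be partly categorical (integer-coded modes), for
# which successive differences and least-squares slopes are ill-defined;
# those four members are dropped, leaving 31.
VENTILATOR_DROP <- c("mean_abs_successive_diff", "max_abs_successive_diff",
                     "slope_overall", "slope_last24h")
VENTILATOR_FEATURES <- setdiff(NUMERIC_SERIES_FEATURES, VENTILATOR_DROP)

MEDICATION_FEATURES <- c(
  "ever_given", "n_administrations", "n_last24h", "time_since_last_dose",
  "last_dose_value", "cumulative_dose", "dose_trend", "n_distinct_days",
  "time_of_first_administration")

EVENT_FEATURES <- c("ever_recorded", "n_events", "time_since_last",
                    "in_last24h")

IO_FEATURES <- c("total_last24h", "n_measurements")

#' Per-category feature counts
#'
#' The fixed contract: labs/vitals 35, ventilator 31, medications 9,
#' cultures/procedures 4, intake/output 2, atemporal 1.
#' @return Named integer vector.
#' @export
feature_counts <- function() {
  c(labs = length(NUMERIC_SERIES_FEATURES),
    vitals = length(NUMERIC_SERIES_FEATURES),
    ventilator = length(VENTILATOR_FEATURES),
    medications = length(MEDICATION_FEATURES),
    cultures = length(EVENT_FEATURES),
    procedures = length(EVENT_FEATURES),
    intake_output = length(IO_FEATURES),
    demographics = 1L, diagnosis = 1L)
}

category_features <- function(category) {
  switch(category,
         labs = , vitals = NUMERIC_SERIES_FEATURES,
         ventilator = VENTILATOR_FEATURES,
         medications = MEDICATION_FEATURES,
         cultures = , procedures = EVENT_FEATURES,
         intake_output = IO_FEATURES,
         demographics = , diagnosis = "value",
         stopf("unknown variable category '%s'", category))
}

#' Build one variable's feature group
#'
#' Computes the category's fixed feature list from one time-stamped series
#' up to the prediction time. Features undefined for short series (e.g., the
#' last-two difference with fewer than two points, or a standard deviation
#' with one point) are emitted as `NA`. Times are minutes; `time_since_*`
#' features are measured back from the prediction time, `time_of_*` forward
#' from admission. The last-two difference is most-recent minus previous.
#'
#' @param series Data frame with columns `t` (minutes since admission,
#'   nondecreasing) and `value`, or `NULL`/zero-row for a variable with no
#'   data in the case.
#' @param category Variable category (see [feature_counts()]).
#' @param prediction_time Prediction time in minutes since admission.
#' @return Named numeric vector with exactly the category's feature count.
#' @export
build_feature_group <- function(series, category, prediction_time) {
  feats <- category_features(category)
  out <- stats::setNames(rep(NA_real_, length(feats)), feats)
  if (category %in% c("demographics", "diagnosis")) {
    stopf("atemporal variables are encoded by assemble_matrix(), not build_feature_group()")
  }
  empty <- is.null(series) || nrow(series) == 0L
  if (!empty && is.unsorted(series$t)) {
    stopf("series timestamps must be nondecreasing")
  }
  if (empty) {
    # an absent variable still answers "was it ever measured?"
    out[intersect(c("ever_measured", "ever_given", "ever_recorded",
                    "measured_last24h", "in_last24h"), feats)] <- 0
    if (category == "intake_output") out[] <- NA_real_
    return(out)
  }
  t <- series$t; v <- series$value; n <- length(v)
  cutoff <- prediction_time - 1440
  i24 <- t >= cutoff

  if (category %in% c("labs", "vitals", "ventilator")) {
    out["first_value"] <- v[1L]
    out["last_value"] <- v[n]
    out["min_value"] <- min(v)
    out["max_value"] <- max(v)
    out["mean_value"] <- mean(v)
    out["median_value"] <- stats::median(v)
    out["sd_value"] <- if (n >= 2L) stats::sd(v) else NA_real_
    out["iqr_value"] <- if (n >= 2L) stats::IQR(v) else NA_real_
    out["range_value"] <- max(v) - min(v)
    out["diff_last_two"] <- if (n >= 2L) v[n] - v[n - 1L] else NA_real_
    out["diff_first_last"] <- v[n] - v[1L]
    out["time_since_first"] <- prediction_time - t[1L]
    out["time_since_last"] <- prediction_time - t[n]
    out["time_of_min"] <- t[which.min(v)]
    out["time_of_max"] <- t[which.max(v)]
    out["time_since_min"] <- prediction_time - t[which.min(v)]
    out["time_since_max"] <- prediction_time - t[which.max(v)]
    out["gap_last_two"] <- if (n >= 2L) t[n] - t[n - 1L] else NA_real_
    out["mean_gap"] <- if (n >= 2L) mean(diff(t)) else NA_real_
    out["n_measurements"] <- n
    out["measurement_rate"] <- n / max(prediction_time, 1)
    out["ever_measured"] <- 1
    out["n_last24h"] <- sum(i24)
    out["mean_last24h"] <- if (any(i24)) mean(v[i24]) else NA_real_
    out["min_last24h"] <- if (any(i24)) min(v[i24]) else NA_real_
    out["max_last24h"] <- if (any(i24)) max(v[i24]) else NA_real_
    out["sd_last24h"] <- if (sum(i24) >= 2L) stats::sd(v[i24]) else NA_real_
    out["measured_last24h"] <- as.numeric(any(i24))
    m <- mean(v)
    cs <- sign(v - m)
    out["n_crossings_mean"] <- if (n >= 2L) sum(cs[-1L] * cs[-n] < 0) else 0
    out["frac_above_mean"] <- mean(v > m)
    out["last_minus_mean"] <- v[n] - m
    if (category != "ventilator") {
      out["mean_abs_successive_diff"] <- if (n >= 2L) mean(abs(diff(v))) else NA_real_
      out["max_abs_successive_diff"] <- if (n >= 2L) max(abs(diff(v))) else NA_real_
      out["slope_overall"] <- ls_slope(t, v)
      out["slope_last24h"] <- if (sum(i24) >= 2L) ls_slope(t[i24], v[i24]) else NA_real_
    }
  } else if (category == "medications") {
    out["ever_given"] <- 1
    out["n_administrations"] <- n
    out["n_last24h"] <- sum(i24)
    out["time_since_last_dose"] <- prediction_time - t[n]
    out["last_dose_value"] <- v[n]
    out["cumulative_dose"] <- sum(v)
    out["dose_trend"] <- v[n] - v[1L]
    out["n_distinct_days"] <- length(unique(floor(t / 1440)))
    out["time_of_first_administration"] <- t[1L]
  } else if (category %in% c("cultures", "procedures")) {
    out["ever_recorded"] <- 1
    out["n_events"] <- n
    out["time_since_last"] <- prediction_time - t[n]
    out["in_last24h"] <- as.numeric(any(i24))
  } else if (category == "intake_output") {
    out["total_last24h"] <- if (any(i24)) sum(v[i24]) else 0
    out["n_measurements"] <- n
  }
  out
}

# least-squares slope of value on time; NA when degenerate
ls_slope <- function(t, v) {
  if (length(t) < 2L || stats::sd(t) == 0) return(NA_real_)
  stats::cov(t, v) / stats::var(t)
}

#' Feature schema for a variable inventory
#'
#' The canonical, stable ordering of the full feature vector: variables in
#' inventory order, each contributing its category's fixed feature list.
#'
#' @param inventory A [variable_inventory()] data frame (columns `item_id`,
#'   `category` suffice).
#' @return Data frame with columns `feature` (`"<variable>.<name>"`),
#'   `variable_id`, `category`, `type` (`numeric` or `nominal`).
#' @export
feature_schema <- function(inventory) {
  nominal <- c("ever_measured", "measured_last24h", "ever_given",
               "ever_recorded", "in_last24h", "value")
  parts <- lapply(seq_len(nrow(inventory)), function(i) {
    cat <- inventory$category[i]
    feats <- category_features(cat)
    data.frame(feature = paste(inventory$item_id[i], feats, sep = "."),
               variable_id = inventory$item_id[i],
               category = cat,
               type = ifelse(feats %in% nominal &
                               cat %in% c("demographics", "diagnosis",
                                          "labs", "vitals", "ventilator",
                                          "medications", "cultures",
                                          "procedures"),
                             "nominal", "numeric"),
               stringsAsFactors = FALSE)
  })
  sch <- do.call(rbind, parts)
  # continuous atemporal demographics stay numeric; coded categoricals are
  # nominal (sex, unit, race) as is the diagnosis indicator
  num_demo <- c("demo_age", "demo_weight", "demo_height")
  sch$type[sch$variable_id %in% num_demo] <- "numeric"
  stopifnot(!anyDuplicated(sch$feature))
  counts <- feature_counts()
  for (cat in unique(sch$category)) {
    per_var <- table(sch$variable_id[sch$category == cat])
    stopifnot(all(per_var == counts[[cat]]))
  }
  rownames(sch) <- NULL
  sch
}

# integer-code an atemporal value against (and growing) a codebook
encode_atemporal <- function(value, codebook, key) {
  if (is.numeric(value)) return(list(value = as.numeric(value), codebook = codebook))
  cb <- codebook[[key]]
  if (is.null(cb)) cb <- character(0)
  if (!value %in% cb) cb <- c(cb, value)
  codebook[[key]] <- cb
  list(value = as.numeric(match(value, cb)), codebook = codebook)
}

#' Assemble the case-by-feature matrix for a cohort
#'
#' Builds each case's fixed-width feature vector under the cohort's schema.
#' Variables absent in a case fill their group with `NA`, except the
#' ever-measured/ever-given/ever-recorded flag, which is 0 (absence of data
#' is itself the answer to "was it ever measured?"). Atemporal categoricals
#' are integer-coded with a stored codebook.
#'
#' @param cohort An `icu_cohort`, or a list of cases plus an `inventory`.
#' @param inventory Required when `cohort` is a bare list of cases.
#' @return Object of class `feature_matrix`: a numeric matrix (cases x
#'   features, `NA` = missing) with attributes `schema` (see
#'   [feature_schema()]) and `codebooks`.
#' @export
assemble_matrix <- function(cohort, inventory = NULL) {
  if (inherits(cohort, "icu_cohort")) {
    cases <- cohort$cases
    inventory <- cohort$inventory
  } else {
    cases <- cohort
    if (is.null(inventory)) stopf("'inventory' is required for a bare case list")
  }
  sch <- feature_schema(inventory)
  codebooks <- list()
  m <- matrix(NA_real_, nrow = length(cases), ncol = nrow(sch),
              dimnames = list(vapply(cases, `[[`, "", "case_id"), sch$feature))
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    extra <- setdiff(names(case$series), inventory$item_id)
    if (length(extra) > 0L) {
      stopf("case %s has variables outside the shared inventory: %s",
            case$case_id, paste(extra, collapse = ", "))
    }
    row <- stats::setNames(rep(NA_real_, nrow(sch)), sch$feature)
    for (vi in which(inventory$is_target)) {
      vid <- inventory$item_id[vi]
      g <- build_feature_group(case$series[[vid]], inventory$category[vi],
                               case$prediction_time)
      row[paste(vid, names(g), sep = ".")] <- g
    }
    for (vid in inventory$item_id[inventory$category == "demographics"]) {
      val <- case$demographics[[vid]]
      if (!is.null(val)) {
        enc <- encode_atemporal(val, codebooks, vid)
        codebooks <- enc$codebook
        row[paste0(vid, ".value")] <- enc$value
      }
    }
    if ("diagnosis" %in% inventory$item_id) {
      row["diagnosis.value"] <- as.numeric(case$diagnosis == "AKF")
    }
    m[ci, ] <- row
  }
  structure(m, schema = sch, codebooks = codebooks, class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("Feature matrix: %d cases x %d features (%d variables, %.1f%% missing)\n",
              nrow(x), ncol(x), length(unique(sch$variable_id)),
              100 * mean(is.na(x))))
  invisible(x)
}

# subset columns of a feature_matrix, keeping schema/codebooks in sync
subset_features <- function(m, keep) {
  sch <- attr(x <- m, "schema")
  out <- unclass(m)[, keep, drop = FALSE]
  structure(out,
            schema = sch[match(colnames(out), sch$feature), , drop = FALSE],
            codebooks = attr(m, "codebooks"),
            imputation = attr(m, "imputation"),
            class = "feature_matrix")
}
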