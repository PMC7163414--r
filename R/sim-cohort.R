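# Synthetic ICU cohort generator: variable inventory, patient cases, and the
# latent relevance model that links case summaries to item relevance.

CATEGORY_PREFIX <- c(vitals = "vit", ventilator = "vent", labs = "lab",
                     medications = "med", procedures = "proc",
                     cultures = "cult", intake_output = "io")

# Mean observation counts per category (Poisson + 1), chosen to resemble the
# relative charting density of an ICU stay at a desk-testable scale.
OBS_LAMBDA <- c(vitals = 16, ventilator = 10, labs = 6, medications = 4,
                procedures = 2, cultures = 1, intake_output = 8)

DEMOGRAPHIC_IDS <- c("demo_age", "demo_sex", "demo_weight", "demo_height",
                     "demo_unit", "demo_race")

#' Build the variable inventory implied by a configuration
#'
#' One row per variable: its identifier, category, reference range, the
#' diagnosis it is most associated with, and whether it is a labeling target
#' (time-series variables are targets; demographics and diagnosis are
#' predictors only).
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `item_id`, `category`, `ref_lo`,
#'   `ref_hi`, `affinity`, `is_target`.
#' @export
variable_inventory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$variable_counts
  rows <- list()
  with_seed(derive_seed(config$seed, 1L), {
    for (cat in names(CATEGORY_PREFIX)) {
      n <- counts[[cat]]
      if (n == 0L) next
      ids <- sprintf("%s_%02d", CATEGORY_PREFIX[[cat]], seq_len(n))
      lo <- stats::runif(n, 10, 100)
      width <- stats::runif(n, 5, 40)
      if (cat == "cultures") {      # value 1 = growth; growth is "abnormal"
        lo <- rep(-0.5, n); width <- rep(1, n)
      }
      rows[[cat]] <- data.frame(
        item_id = ids, category = cat,
        ref_lo = lo, ref_hi = lo + width,
        affinity = sample(c("AKF", "ARF"), n, replace = TRUE),
        is_target = TRUE, stringsAsFactors = FALSE)
    }
  })
  atem <- data.frame(
    item_id = c(DEMOGRAPHIC_IDS[seq_len(min(counts[["demographics"]], 6L))],
                if (counts[["diagnosis"]] > 0L) "diagnosis"),
    category = c(rep("demographics", min(counts[["demographics"]], 6L)),
                 if (counts[["diagnosis"]] > 0L) "diagnosis"),
    ref_lo = NA_real_, ref_hi = NA_real_, affinity = NA_character_,
    is_target = FALSE, stringsAsFactors = FALSE)
  inv <- rbind(do.call(rbind, rows), atem)
  rownames(inv) <- NULL
  inv
}

#' Construct the latent relevance model
#'
#' A deterministic logistic map from three case summaries — measured within
#' the last 24 h, latest value abnormal, diagnosis matches the item's
#' affinity — to a per-item relevance probability.
#'
#' @param inventory A [variable_inventory()] data frame.
#' @param coef Named coefficient vector
#'   `c(intercept, recent, abnormal, diagnosis)`.
#' @return An object of class `relevance_model`.
#' @export
relevance_model <- function(inventory, coef) {
  items <- inventory$item_id[inventory$is_target]
  cm <- matrix(rep(coef[c("intercept", "recent", "abnormal", "diagnosis")],
                   each = length(items)),
               nrow = length(items),
               dimnames = list(items,
                               c("intercept", "recent", "abnormal", "diagnosis")))
  structure(list(coef = cm, inventory = inventory),
            class = "relevance_model")
}

#' @export
print.relevance_model <- function(x, ...) {
  cat(sprintf("Latent relevance model over %d items\n", nrow(x$coef)))
  cat("  logit(p) = intercept + b1*recent + b2*abnormal + b3*diag_match\n")
  cat(sprintf("  coefficients (shared): %s\n",
              paste(sprintf("%s=%.2f", colnames(x$coef), x$coef[1, ]),
                    collapse = " ")))
  invisible(x)
}

#' Generate a synthetic ICU cohort
#'
#' Draws `n_cases` patient cases with roughly balanced AKF/ARF diagnoses.
#' Each time-series variable is present with probability `1 - missing_rate`;
#' when present, its series is constructed so that the two latent covariates
#' (recently measured, latest value abnormal) are exactly recoverable from
#' the data. Identical configurations reproduce identical cohorts.
#'
#' @param config A [sim_config()].
#' @param model Optionally, a [relevance_model()] to reuse (for generating an
#'   evaluation cohort under the same ground truth).
#' @return An object of class `icu_cohort`: a list with `cases`, `model`,
#'   `inventory`, `config`.
#' @export
generate_cohort <- function(config, model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  inventory <- if (is.null(model)) variable_inventory(config) else model$inventory
  if (is.null(model)) {
    model <- relevance_model(inventory, config$relevance_coef)
  }
  pred_t <- config$prediction_time_min
  ts_inv <- inventory[inventory$is_target, , drop = FALSE]

  cases <- with_seed(derive_seed(config$seed, 2L), {
    lapply(seq_len(config$n_cases), function(i) {
      diagnosis <- if (i %% 2L == 1L) "AKF" else "ARF"
      demo <- list(
        demo_age = round(stats::runif(1, 25, 90)),
        demo_sex = sample(c("F", "M"), 1L),
        demo_weight = round(stats::runif(1, 45, 140), 1),
        demo_height = round(stats::runif(1, 145, 200), 1),
        demo_unit = sample(c("MICU", "SICU", "CTICU"), 1L),
        demo_race = sample(c("white", "black", "asian", "other"), 1L)
      )[seq_len(sum(inventory$category == "demographics"))]
      series <- list()
      for (k in seq_len(nrow(ts_inv))) {
        if (stats::runif(1) < config$missing_rate) next
        v <- ts_inv[k, ]
        series[[v$item_id]] <- simulate_series(
          v, pred_t, config$p_recent, config$p_abnormal)
      }
      list(case_id = sprintf("case_%04d", i),
           diagnosis = diagnosis,
           demographics = demo,
           series = series,
           admission_time = 0,
           prediction_time = pred_t)
    })
  })
  structure(list(cases = cases, model = model, inventory = inventory,
                 config = config),
            class = "icu_cohort")
}

# One variable's time-stamped series; draws the latent recent/abnormal flags
# first, then builds timestamps and values consistent with them.
simulate_series <- function(vrow, pred_t, p_recent, p_abnormal) {
  recent <- stats::runif(1) < p_recent
  abnormal <- stats::runif(1) < p_abnormal
  n <- stats::rpois(1, OBS_LAMBDA[[vrow$category]]) + 1L
  t_last <- if (recent) stats::runif(1, pred_t - 1440, pred_t) else
    stats::runif(1, 1, pred_t - 1440)
  t <- if (n > 1L) sort(stats::runif(n - 1L, 0, t_last)) else numeric()
  t <- c(t, t_last)
  lo <- vrow$ref_lo; hi <- vrow$ref_hi
  mid <- (lo + hi) / 2; width <- hi - lo
  if (vrow$category == "cultures") {
    value <- stats::rbinom(n, 1L, 0.2)
    value[n] <- as.integer(abnormal)
  } else {
    value <- stats::rnorm(n, mid, width / 4)
    value[n] <- if (abnormal) {
      side <- sample(c(-1, 1), 1L)
      mid + side * width * (0.55 + 0.35 * stats::runif(1))
    } else {
      stats::runif(1, lo + 0.02 * width, hi - 0.02 * width)
    }
  }
  data.frame(t = t, value = value)
}

#' Latent case summaries for one item
#'
#' The three covariates of the relevance model, computed from the case data:
#' recently measured (last observation within 24 h of prediction time),
#' latest value outside the item's reference range, and diagnosis match.
#' Returns `NULL` when the item has no data in the case.
#' @param case A patient case (element of `cohort$cases`).
#' @param inventory The cohort's variable inventory.
#' @param item_id Variable identifier.
#' @return Named numeric vector `c(recent, abnormal, diagnosis)` or `NULL`.
#' @export
case_item_summaries <- function(case, inventory, item_id) {
  s <- case$series[[item_id]]
  if (is.null(s)) return(NULL)
  v <- inventory[inventory$item_id == item_id, ]
  if (nrow(v) != 1L) stopf("item '%s' not in the variable inventory", item_id)
  last_t <- s$t[nrow(s)]
  last_val <- s$value[nrow(s)]
  c(recent = as.numeric(last_t >= case$prediction_time - 1440),
    abnormal = as.numeric(last_val < v$ref_lo | last_val > v$ref_hi),
    diagnosis = as.numeric(identical(case$diagnosis, v$affinity)))
}

#' True relevance probabilities for a case
#'
#' Applies the latent relevance model to one case. Items with no data in the
#' case are marked absent (`NA`); all other probabilities lie in `[0, 1]`.
#'
#' @param case A patient case.
#' @param model A [relevance_model()].
#' @return Named numeric vector over the model's items; `NA` marks absent.
#' @export
true_relevance <- function(case, model) {
  stopifnot(inherits(model, "relevance_model"))
  items <- rownames(model$coef)
  unknown <- setdiff(names(case$series), items)
  if (length(unknown) > 0L) {
    stopf("case contains items unknown to the relevance model: %s",
          paste(unknown, collapse = ", "))
  }
  p <- stats::setNames(rep(NA_real_, length(items)), items)
  for (it in items) {
    z <- case_item_summaries(case, model$inventory, it)
    if (is.null(z)) next
    b <- model$coef[it, ]
    p[[it]] <- stats::plogis(b[["intercept"]] + sum(b[c("recent", "abnormal",
                                                        "diagnosis")] * z))
  }
  p
}

#' @export
print.icu_cohort <- function(x, ...) {
  dg <- table(vapply(x$cases, `[[`, "", "diagnosis"))
  cat(sprintf("Synthetic ICU cohort: %d cases (%s), %d variables (%d targets)\n",
              length(x$cases),
              paste(sprintf("%s=%d", names(dg), dg), collapse = ", "),
              nrow(x$inventory), sum(x$inventory$is_target)))
  invisible(x)
}
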