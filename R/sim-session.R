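# Review-session simulator: a 60 Hz gaze stream over a scrolling layout,
# plus checkbox selections, with known intended dwell per item.

ELEMENT_X0 <- 100
ELEMENT_X1 <- 900
ELEMENT_HEIGHT <- 80
ELEMENT_PITCH <- 90
PAGE_TOP <- 100
VIEWPORT_HEIGHT <- 1080
SNAPSHOT_INTERVAL_MS <- 2000
TRANSITION_SAMPLES <- 3L

#' Simulate one review session for a case
#'
#' For each item present in the case, a relevance draw `Bernoulli(p)` decides
#' whether the intended gaze dwell is drawn from the relevant-mode or the
#' irrelevant-mode lognormal distribution. Gaze is emitted as fixation bouts:
#' consecutive samples inside the item's rectangle (as positioned by the
#' layout snapshot in force at each sample time), separated by brief
#' transition samples attributed to no element. The interface scrolls:
#' layout snapshots every 2 s shift element rectangles vertically, and the
#' synthesized gaze tracks the moving rectangles. Manual selections are the
#' relevance draws with independent flips at `manual_flip_noise`. Sessions
#' may be marked `gaze_incomplete` (most samples invalid) or
#' `selection_skipped` (no selection record) with the configured
#' probabilities.
#'
#' @param case A patient case from [generate_cohort()].
#' @param relevance Named relevance-probability vector from
#'   [true_relevance()] for this case.
#' @param config The [sim_config()] in force.
#' @param seed Integer seed for this session.
#' @return An object of class `review_session`: list with `case_id`, `gaze`
#'   (data frame `timestamp_ms`, `x_px`, `y_px`, `valid`), `layout` (list of
#'   snapshots, each `list(timestamp_ms, elements)`), `manual_selections`
#'   (character vector, or `NULL` when the selection task was skipped),
#'   `qc_flags`, `present_items`, and `intended` (data frame of per-item
#'   relevance draws and intended dwell in ms).
#' @export
simulate_session <- function(case, relevance, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  present <- names(relevance)[!is.na(relevance)]
  if (!all(present %in% names(case$series))) {
    stopf("relevance vector does not match the case's present items")
  }
  period <- 1000 / config$sample_rate
  dl <- config$dwell_lognormal_params

  with_seed(seed, {
    rel <- stats::rbinom(length(present), 1L, relevance[present]) == 1L
    mu <- ifelse(rel, dl[["mu_rel"]], dl[["mu_irr"]])
    dwell <- stats::rlnorm(length(present), meanlog = log(mu),
                           sdlog = dl[["sigma"]])
    if (sum(dwell) > config$session_duration * 1000) {
      stopf(paste0("simulation infeasible: intended dwells total %.0f ms but ",
                   "session_duration is %.0f ms"),
            sum(dwell), config$session_duration * 1000)
    }
    n_samples <- round(dwell / period)
    needed_ms <- sum(n_samples + TRANSITION_SAMPLES) * period
    if (needed_ms > config$session_duration * 1000) {
      stopf(paste0("simulation infeasible: emitting the intended dwells needs ",
                   "%.0f ms but session_duration is %.0f ms"),
            needed_ms, config$session_duration * 1000)
    }

    layout <- build_layout_stream(present, config$session_duration * 1000)
    snap_times <- vapply(layout, `[[`, 0, "timestamp_ms")

    ts <- x <- y <- numeric(0)
    t_cur <- 0
    for (k in seq_along(present)) {
      nk <- n_samples[k]
      if (nk > 0L) {
        tk <- t_cur + (seq_len(nk) - 1L) * period
        si <- findInterval(tk, snap_times)
        jx <- stats::runif(nk, -0.45, 0.45) * (ELEMENT_X1 - ELEMENT_X0)
        jy <- stats::runif(nk, -0.45, 0.45) * ELEMENT_HEIGHT
        px <- py <- numeric(nk)
        for (j in seq_len(nk)) {
          el <- layout[[si[j]]]$elements
          r <- el[el$item_id == present[k], ]
          px[j] <- (r$x0 + r$x1) / 2 + jx[j]
          py[j] <- (r$y0 + r$y1) / 2 + jy[j]
        }
        ts <- c(ts, tk); x <- c(x, px); y <- c(y, py)
        t_cur <- t_cur + nk * period
      }
      tt <- t_cur + (seq_len(TRANSITION_SAMPLES) - 1L) * period
      ts <- c(ts, tt)
      x <- c(x, rep(ELEMENT_X0 / 2, TRANSITION_SAMPLES))
      y <- c(y, stats::runif(TRANSITION_SAMPLES, 0, VIEWPORT_HEIGHT))
      t_cur <- t_cur + TRANSITION_SAMPLES * period
    }
    valid <- rep(1L, length(ts))
    qc_flags <- character(0)
    if (stats::runif(1) < config$p_gaze_incomplete) {
      qc_flags <- c(qc_flags, "gaze_incomplete")
      valid[stats::runif(length(valid)) < 0.6] <- 0L
    }
    flips <- stats::runif(length(present)) < config$manual_flip_noise
    selected <- xor(rel, flips)
    manual <- present[selected]
    if (stats::runif(1) < config$p_selection_skipped) {
      qc_flags <- c(qc_flags, "selection_skipped")
      manual <- NULL
    }
    structure(list(
      case_id = case$case_id,
      gaze = data.frame(timestamp_ms = ts, x_px = x, y_px = y, valid = valid),
      layout = layout,
      manual_selections = manual,
      qc_flags = qc_flags,
      present_items = present,
      intended = data.frame(item_id = present, relevant = rel,
                            dwell_ms = dwell, stringsAsFactors = FALSE)
    ), class = "review_session")
  })
}

# Discrete layout snapshots every 2 s; the page scrolls linearly from top to
# bottom over the session, shifting every element rectangle vertically.
build_layout_stream <- function(items, duration_ms) {
  page_y0 <- PAGE_TOP + (seq_along(items) - 1L) * ELEMENT_PITCH
  page_height <- PAGE_TOP + length(items) * ELEMENT_PITCH
  max_scroll <- max(0, page_height - VIEWPORT_HEIGHT)
  snap_times <- seq(0, duration_ms, by = SNAPSHOT_INTERVAL_MS)
  lapply(snap_times, function(tm) {
    scroll <- if (duration_ms > 0) max_scroll * tm / duration_ms else 0
    list(timestamp_ms = tm,
         elements = data.frame(
           item_id = items,
           x0 = ELEMENT_X0, y0 = page_y0 - scroll,
           x1 = ELEMENT_X1, y1 = page_y0 - scroll + ELEMENT_HEIGHT,
           stringsAsFactors = FALSE))
  })
}

#' @export
print.review_session <- function(x, ...) {
  cat(sprintf("Review session for %s: %d gaze samples, %d items, %s\n",
              x$case_id, nrow(x$gaze), length(x$present_items),
              if (length(x$qc_flags)) paste("QC flags:",
                                            paste(x$qc_flags, collapse = ", "))
              else "QC clean"))
  invisible(x)
}
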