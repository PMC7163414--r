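# Dynamic area-of-interest gaze processing: attribute gaze samples to
# interface elements, accumulate per-item dwell, derive labels, and apply
# session quality control.

#' Attribute one gaze sample to an interface element
#'
#' Containment is half-open in screen-pixel coordinates (origin top-left,
#' y increasing downward): a point belongs to a rectangle when
#' `x0 <= x < x1` and `y0 <= y < y1`. Invalid samples attribute to nothing.
#' When overlapping rectangles both contain the point, the first element in
#' snapshot order wins and a warning is raised.
#'
#' @param sample List or one-row data frame with `timestamp_ms`, `x_px`,
#'   `y_px`, `valid`.
#' @param snapshot Layout snapshot: `list(timestamp_ms, elements)` where
#'   `elements` has columns `item_id`, `x0`, `y0`, `x1`, `y1`.
#' @return The containing element's `item_id`, or `NA_character_`.
#' @export
attribute_sample <- function(sample, snapshot) {
  if (snapshot$timestamp_ms > sample$timestamp_ms) {
    stopf("snapshot at %s ms postdates the gaze sample at %s ms",
          format(snapshot$timestamp_ms), format(sample$timestamp_ms))
  }
  if (!isTRUE(sample$valid == 1) && !isTRUE(sample$valid)) {
    return(NA_character_)
  }
  el <- snapshot$elements
  hit <- which(el$x0 <= sample$x_px & sample$x_px < el$x1 &
               el$y0 <= sample$y_px & sample$y_px < el$y1)
  if (length(hit) == 0L) return(NA_character_)
  if (length(hit) > 1L) {
    warnf("gaze point (%.1f, %.1f) inside %d overlapping elements; first wins",
          sample$x_px, sample$y_px, length(hit))
  }
  el$item_id[hit[1L]]
}

#' Accumulate per-item gaze dwell over a session
#'
#' Each valid sample is attributed to an element using the latest layout
#' snapshot at or before the sample's timestamp, and contributes
#' `min(next_timestamp - timestamp, max_gap_ms)` to that element's dwell.
#' The last sample contributes the nominal sample period. Invalid samples
#' contribute nothing.
#'
#' @param gaze Data frame `timestamp_ms`, `x_px`, `y_px`, `valid`, strictly
#'   increasing timestamps.
#' @param layout List of layout snapshots, time-sorted; the first snapshot
#'   must not postdate the first gaze sample.
#' @param max_gap_ms Cap on a single sample's contribution; guards against
#'   tracking dropouts being credited as dwell.
#' @param nominal_period_ms Contribution of the final sample; defaults to
#'   the median inter-sample interval (or 1000/60 for a single sample).
#' @return Object of class `dwell_table`: named numeric vector of dwell in
#'   ms over the items appearing in the layout, with attribute
#'   `session_duration_ms`.
#' @export
compute_dwell <- function(gaze, layout, max_gap_ms = 100,
                          nominal_period_ms = NULL) {
  if (nrow(gaze) == 0L || length(layout) == 0L) {
    stopf("gaze and layout streams must be nonempty")
  }
  if (is.unsorted(gaze$timestamp_ms, strictly = TRUE)) {
    stopf("gaze timestamps must be strictly increasing")
  }
  snap_times <- vapply(layout, `[[`, 0, "timestamp_ms")
  if (is.unsorted(snap_times)) stopf("layout snapshots must be time-sorted")
  if (snap_times[1L] > gaze$timestamp_ms[1L]) {
    stopf("no layout snapshot precedes the gaze sample at %s ms",
          format(gaze$timestamp_ms[1L]))
  }
  items <- unique(unlist(lapply(layout, function(s) s$elements$item_id)))
  dwell <- stats::setNames(numeric(length(items)), items)

  n <- nrow(gaze)
  if (is.null(nominal_period_ms)) {
    nominal_period_ms <- if (n >= 2L) stats::median(diff(gaze$timestamp_ms))
                         else 1000 / 60
  }
  contrib <- c(pmin(diff(gaze$timestamp_ms), max_gap_ms),
               min(nominal_period_ms, max_gap_ms))
  snap_idx <- findInterval(gaze$timestamp_ms, snap_times)
  valid <- gaze$valid == 1

  overlap_warned <- FALSE
  for (si in unique(snap_idx)) {
    sel <- which(snap_idx == si & valid)
    if (length(sel) == 0L) next
    el <- layout[[si]]$elements
    px <- gaze$x_px[sel]; py <- gaze$y_px[sel]
    assigned <- rep(NA_integer_, length(sel))
    hits <- 0L
    # first element in snapshot order wins; scan in reverse so earlier
    # elements overwrite later ones
    for (e in rev(seq_len(nrow(el)))) {
      inside <- el$x0[e] <= px & px < el$x1[e] & el$y0[e] <= py & py < el$y1[e]
      hits <- hits + sum(inside & !is.na(assigned))
      assigned[inside] <- e
    }
    if (hits > 0L && !overlap_warned) {
      warnf("%d gaze samples fell inside overlapping elements; first element in snapshot order wins", hits)
      overlap_warned <- TRUE
    }
    ok <- !is.na(assigned)
    if (any(ok)) {
      add <- tapply(contrib[sel[ok]], el$item_id[assigned[ok]], sum)
      dwell[names(add)] <- dwell[names(add)] + add
    }
  }
  structure(dwell, class = "dwell_table",
            session_duration_ms =
              gaze$timestamp_ms[n] - gaze$timestamp_ms[1L] + nominal_period_ms)
}

#' @export
print.dwell_table <- function(x, ...) {
  cat(sprintf("Dwell table: %d items, total %.0f ms (session %.0f ms)\n",
              length(x), sum(x), attr(x, "session_duration_ms")))
  print(round(unclass(x)[order(-unclass(x))][seq_len(min(10L, length(x)))]))
  invisible(x)
}

#' Gaze-derived relevance labels from a dwell table
#'
#' An item is labeled positive when its accumulated dwell reaches the
#' threshold (inclusive: a dwell of exactly 250 ms is positive), negative
#' when it falls short, and absent when the item has no data in the case.
#'
#' @param dwell A [compute_dwell()] table (or named numeric vector of ms).
#' @param present_items Items that have data in this case.
#' @param threshold_ms Dwell threshold in ms; 250 ms is the reading-fixation
#'   default.
#' @param universe All items that could carry a target; items in the
#'   universe but not present in the case are labeled `absent`. Defaults to
#'   `present_items` (no absent entries).
#' @return Object of class `label_set`: named character vector over the
#'   universe with values `positive`, `negative`, `absent`, and attribute
#'   `source = "gaze"`.
#' @export
derive_gaze_labels <- function(dwell, present_items, threshold_ms = 250,
                               universe = present_items) {
  if (threshold_ms <= 0) stopf("'threshold_ms' must be > 0")
  unknown <- setdiff(names(dwell), present_items)
  if (length(unknown) > 0L) {
    stopf("dwell table contains items outside the layout universe: %s",
          paste(unknown, collapse = ", "))
  }
  lab <- init_labels(present_items, universe)
  d <- stats::setNames(as.numeric(dwell), names(dwell))
  pos <- names(d)[d >= threshold_ms]
  lab[intersect(pos, present_items)] <- "positive"
  structure(lab, class = "label_set", source = "gaze")
}

init_labels <- function(present_items, universe) {
  if (!all(present_items %in% universe)) {
    stopf("'present_items' must be a subset of 'universe'")
  }
  lab <- stats::setNames(rep("absent", length(universe)), universe)
  lab[present_items] <- "negative"
  lab
}

#' Manual-selection relevance labels
#'
#' Positive for selected items, negative for the remaining present items.
#'
#' @param selections Item ids the reviewer checked; must be a subset of
#'   `present_items` (a violation signals a corrupted session).
#' @param present_items Items that have data in this case.
#' @param universe As in [derive_gaze_labels()].
#' @return A `label_set` with attribute `source = "manual"`.
#' @export
derive_manual_labels <- function(selections, present_items,
                                 universe = present_items) {
  selections <- as.character(selections)
  bad <- setdiff(selections, present_items)
  if (length(bad) > 0L) {
    stopf("selections reference items not present in the case: %s",
          paste(bad, collapse = ", "))
  }
  lab <- init_labels(present_items, universe)
  lab[selections] <- "positive"
  structure(lab, class = "label_set", source = "manual")
}

#' @export
print.label_set <- function(x, ...) {
  tb <- table(factor(unclass(x), levels = c("positive", "negative", "absent")))
  cat(sprintf("%s labels: %d positive, %d negative, %d absent\n",
              attr(x, "source") %||% "?", tb[["positive"]], tb[["negative"]],
              tb[["absent"]]))
  invisible(x)
}

#' Session quality control
#'
#' Flags a session as invalid when gaze capture was incomplete (fraction of
#' valid samples below `min_valid_fraction`, or an empty gaze stream) or the
#' selection task was skipped (no selection record). QC never throws; it
#' reports.
#'
#' @param session A `review_session`.
#' @param min_valid_fraction Minimum fraction of valid gaze samples.
#' @return List of class `session_qc`: `valid`, `reasons`,
#'   `valid_sample_fraction`.
#' @export
qc_session <- function(session, min_valid_fraction = 0.5) {
  reasons <- character(0)
  frac <- if (nrow(session$gaze) == 0L) 0 else mean(session$gaze$valid == 1)
  if (nrow(session$gaze) == 0L || frac < min_valid_fraction) {
    reasons <- c(reasons, "gaze_incomplete")
  }
  if (is.null(session$manual_selections)) {
    reasons <- c(reasons, "selection_skipped")
  }
  structure(list(valid = length(reasons) == 0L, reasons = reasons,
                 valid_sample_fraction = frac),
            class = "session_qc")
}

#' @export
print.session_qc <- function(x, ...) {
  cat(sprintf("Session QC: %s (%.0f%% valid samples)%s\n",
              if (x$valid) "valid" else "invalid",
              100 * x$valid_sample_fraction,
              if (length(x$reasons)) paste0("; reasons: ",
                                            paste(x$reasons, collapse = ", "))
              else ""))
  invisible(x)
}
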