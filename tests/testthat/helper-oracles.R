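# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately share no code with the package
# internals they check.

# naive per-sample dwell accumulation: for each valid sample, find the
# latest snapshot at or before it, scan elements in order for the first
# rectangle containing the point (half-open), and add
# min(next_t - t, max_gap) (nominal period for the last sample).
oracle_dwell <- function(gaze, layout, max_gap_ms = 100,
                         nominal_period_ms = NULL) {
  snap_t <- vapply(layout, function(s) s$timestamp_ms, 0)
  items <- unique(unlist(lapply(layout, function(s) s$elements$item_id)))
  dwell <- setNames(numeric(length(items)), items)
  n <- nrow(gaze)
  if (is.null(nominal_period_ms)) {
    nominal_period_ms <- if (n >= 2) median(diff(gaze$timestamp_ms)) else 1000 / 60
  }
  for (i in seq_len(n)) {
    if (gaze$valid[i] != 1) next
    contrib <- if (i < n) min(gaze$timestamp_ms[i + 1] - gaze$timestamp_ms[i],
                              max_gap_ms) else min(nominal_period_ms, max_gap_ms)
    si <- max(which(snap_t <= gaze$timestamp_ms[i]))
    el <- layout[[si]]$elements
    for (e in seq_len(nrow(el))) {
      if (el$x0[e] <= gaze$x_px[i] && gaze$x_px[i] < el$x1[e] &&
          el$y0[e] <= gaze$y_px[i] && gaze$y_px[i] < el$y1[e]) {
        dwell[[el$item_id[e]]] <- dwell[[el$item_id[e]]] + contrib
        break
      }
    }
  }
  dwell
}

# all positive x negative pairs, ties counted half
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (valid for distinct nonzero |differences|, where the exact null applies)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# build a feature_matrix by hand for preprocessing / screening tests
make_fm <- function(values, types = NULL, variable_id = NULL,
                    category = NULL) {
  m <- as.matrix(values)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("case_", seq_len(nrow(m)))
  sch <- data.frame(
    feature = colnames(m),
    variable_id = variable_id %||% colnames(m),
    category = category %||% rep("labs", ncol(m)),
    type = types %||% rep("numeric", ncol(m)),
    stringsAsFactors = FALSE)
  structure(m, schema = sch, codebooks = list(), class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small inventory used wherever a full-size cohort is unnecessary
tiny_counts <- c(vitals = 2L, ventilator = 1L, labs = 3L, medications = 2L,
                 procedures = 1L, cultures = 1L, intake_output = 1L,
                 demographics = 6L, diagnosis = 1L)

# a minimal session-like object for QC tests
fake_session <- function(n_samples = 100, valid_fraction = 1,
                         selections = character(0)) {
  n_invalid <- round(n_samples * (1 - valid_fraction))
  valid <- c(rep(0L, n_invalid), rep(1L, n_samples - n_invalid))
  list(gaze = data.frame(timestamp_ms = seq_len(n_samples) * 16.67,
                         x_px = 0, y_px = 0, valid = valid),
       manual_selections = selections)
}
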