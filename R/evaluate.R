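# Paired evaluation of manual-vs-gaze relevance models: AUROC, paired
# bootstrap confidence intervals, and a cross-target Wilcoxon signed-rank
# comparison.

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a random positive case
#' scores above a random negative one, ties counted half.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("AUROC undefined: labels contain a single class")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired bootstrap confidence intervals for two models' AUROCs
#'
#' Resamples evaluation cases with replacement, applying the same resample
#' to both score vectors (paired), and forms percentile intervals for each
#' model's AUROC and for the per-resample difference
#' (`manual - gaze` when called with that argument order). Resamples that
#' lose one of the label classes are redrawn and counted.
#'
#' @param scores_a,scores_b Score vectors of the two models on the same
#'   evaluation cases.
#' @param labels Binary gold-standard labels for those cases.
#' @param B Number of bootstrap resamples (at least 100; smaller values are
#'   refused as unstable).
#' @param alpha Two-sided miscoverage; 0.05 gives 95% intervals.
#' @param seed RNG seed.
#' @return List with `auroc_a`, `auroc_b` (point estimates), `ci_a`, `ci_b`,
#'   `ci_diff` (length-2 vectors), `significant` (difference CI excludes 0),
#'   and `n_redrawn`.
#' @export
bootstrap_paired_ci <- function(scores_a, scores_b, labels, B = 2000L,
                                alpha = 0.05, seed = 1L) {
  if (B < 100L) stopf("B = %d is too small for a stable interval (need >= 100)", B)
  y <- as.integer(labels)
  n <- length(y)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  if (length(unique(y)) < 2L) stopf("labels contain a single class")
  a <- b <- numeric(B)
  n_redrawn <- 0L
  with_seed(seed, {
    for (i in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
      a[i] <- auroc(scores_a[idx], y[idx])
      b[i] <- auroc(scores_b[idx], y[idx])
    }
  })
  qs <- c(alpha / 2, 1 - alpha / 2)
  ci_diff <- unname(stats::quantile(a - b, qs))
  list(auroc_a = auroc(scores_a, y), auroc_b = auroc(scores_b, y),
       ci_a = unname(stats::quantile(a, qs)),
       ci_b = unname(stats::quantile(b, qs)),
       ci_diff = ci_diff,
       significant = ci_diff[1L] > 0 || ci_diff[2L] < 0,
       n_redrawn = n_redrawn)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences get mid-ranks.
#' The null distribution is exact for small samples without ties and a
#' tie-corrected normal approximation otherwise (the behavior of
#' [stats::wilcox.test()], which performs this test). The degenerate case
#' of all-zero differences is reported as `p = 1` with a flag rather than
#' an error.
#'
#' @param a,b Paired measurement vectors (e.g., per-target AUROCs of the
#'   manual and gaze models).
#' @return List with `statistic` (V), `p_value`, `n_used` (non-zero
#'   differences), `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- a - b
  n_used <- sum(d != 0)
  if (n_used == 0L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = n_used, degenerate = FALSE)
}

#' Build the paired manual-vs-gaze comparison report
#'
#' For each target pair, computes both models' AUROCs on the evaluation
#' cases (gold standard: manual selection), 95% bootstrap CIs, and the
#' paired difference CI; a difference CI excluding zero flags the pair as
#' significant. Across targets, a paired Wilcoxon signed-rank test compares
#' the two AUROC columns. Rows are sorted by manual-model AUROC,
#' descending.
#'
#' @param pairs A list, one element per target: `list(target, scores_manual,
#'   scores_gaze, labels)` where `labels` are the evaluation gold-standard
#'   labels for the cases where the target's item is not absent.
#' @param B,alpha,seed Bootstrap settings, see [bootstrap_paired_ci()].
#' @return Object of class `comparison_report`: list with `table` (one row
#'   per evaluable pair), `wilcoxon`, `n_significant_manual`,
#'   `n_significant_gaze`, `dropped` (targets unevaluable for single-class
#'   labels).
#' @export
build_report <- function(pairs, B = 2000L, alpha = 0.05, seed = 1L) {
  stopifnot(length(pairs) >= 1L)
  rows <- list()
  dropped <- character(0)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    y <- as.integer(p$labels)
    if (length(unique(y)) < 2L) {
      dropped <- c(dropped, p$target)
      next
    }
    ci <- bootstrap_paired_ci(p$scores_manual, p$scores_gaze, y, B = B,
                              alpha = alpha, seed = derive_seed(seed, i))
    rows[[length(rows) + 1L]] <- data.frame(
      target = p$target, n_eval = length(y), n_pos = sum(y == 1L),
      auroc_manual = ci$auroc_a, ci_manual_lo = ci$ci_a[1L],
      ci_manual_hi = ci$ci_a[2L],
      auroc_gaze = ci$auroc_b, ci_gaze_lo = ci$ci_b[1L],
      ci_gaze_hi = ci$ci_b[2L],
      diff_lo = ci$ci_diff[1L], diff_hi = ci$ci_diff[2L],
      significant = ci$significant,
      direction = if (!ci$significant) "none" else
        if (ci$ci_diff[1L] > 0) "manual" else "gaze",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stopf("no evaluable target pairs")
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$auroc_manual), , drop = FALSE]
  rownames(tab) <- NULL
  wx <- wilcoxon_signed_rank(tab$auroc_manual, tab$auroc_gaze)
  structure(list(table = tab, wilcoxon = wx,
                 n_significant_manual = sum(tab$direction == "manual"),
                 n_significant_gaze = sum(tab$direction == "gaze"),
                 dropped = dropped),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Paired evaluation: %d target pairs\n", nrow(x$table)))
  cat(sprintf("  mean AUROC: manual %.3f, gaze %.3f\n",
              mean(x$table$auroc_manual), mean(x$table$auroc_gaze)))
  cat(sprintf("  significant pairs: %d favor manual, %d favor gaze (alpha from difference CI)\n",
              x$n_significant_manual, x$n_significant_gaze))
  cat(sprintf("  paired Wilcoxon signed-rank: V = %g, p = %.3g%s\n",
              x$wilcoxon$statistic, x$wilcoxon$p_value,
              if (x$wilcoxon$degenerate) " (degenerate)" else ""))
  if (length(x$dropped) > 0L) {
    cat(sprintf("  dropped (single-class evaluation labels): %s\n",
                paste(x$dropped, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.comparison_report <- function(object, ...) {
  print(object)
  cat("\n")
  tb <- object$table
  tb[, sapply(tb, is.numeric)] <- round(tb[, sapply(tb, is.numeric)], 3)
  print(utils::head(tb, 20L), row.names = FALSE)
  if (nrow(tb) > 20L) cat(sprintf("  ... %d more rows\n", nrow(tb) - 20L))
  invisible(object)
}

#' Scatter plot of paired AUROCs
#'
#' Manual-model AUROC against gaze-model AUROC, one point per target, with
#' CI whiskers; points above the diagonal favor the gaze-derived model.
#' Significant pairs are drawn as filled triangles.
#'
#' @param x A `comparison_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.comparison_report <- function(x, ...) {
  tb <- x$table
  graphics::plot(tb$auroc_manual, tb$auroc_gaze, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "AUROC, manual-selection model",
                 ylab = "AUROC, gaze-derived model",
                 pch = ifelse(tb$significant, 17, 1),
                 col = ifelse(tb$significant, "red", "black"), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::segments(tb$ci_manual_lo, tb$auroc_gaze, tb$ci_manual_hi,
                     tb$auroc_gaze, col = "grey70")
  graphics::segments(tb$auroc_manual, tb$ci_gaze_lo, tb$auroc_manual,
                     tb$ci_gaze_hi, col = "grey70")
  invisible(x)
}
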