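# Per-item relevance modeling: target eligibility, per-variable feature
# screening, and cross-validated selection over (imputation x classifier)
# candidates, refit on the full training data.

#' Enumerate eligible targets from per-case labels
#'
#' A target (data item) is eligible for model construction when, over cases
#' where it is not absent, it has strictly more than `min_positives`
#' positive labels.
#'
#' @param labels A list of `label_set`s (one per case), all from the same
#'   source, or a case-by-item character matrix of
#'   `positive`/`negative`/`absent`.
#' @param min_positives Eligibility cut: a target needs `> min_positives`
#'   positives (so 4 positives qualify at the default of 3).
#' @return Data frame of class `target_spec`: `item_id`, `source`,
#'   `n_positive`, `n_negative`, `n_absent`, `eligible`.
#' @export
eligible_targets <- function(labels, min_positives = 3L) {
  lm <- label_matrix(labels)
  src <- attr(lm, "source") %||% "unknown"
  n_pos <- colSums(lm == "positive")
  n_neg <- colSums(lm == "negative")
  n_abs <- colSums(lm == "absent")
  out <- data.frame(item_id = colnames(lm), source = src,
                    n_positive = n_pos, n_negative = n_neg, n_absent = n_abs,
                    eligible = n_pos > min_positives,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("target_spec", "data.frame")
  out
}

# stack per-case label sets into a case x item character matrix
label_matrix <- function(labels) {
  if (is.matrix(labels)) return(labels)
  stopifnot(length(labels) > 0L)
  items <- names(labels[[1L]])
  src <- attr(labels[[1L]], "source")
  lm <- do.call(rbind, lapply(labels, function(l) {
    if (!identical(names(l), items)) {
      stopf("label sets do not share one item universe")
    }
    unclass(l)
  }))
  rownames(lm) <- names(labels)
  structure(lm, source = src)
}

# stratified k-fold assignment, deterministic under seed; k is reduced when
# a class has fewer members than folds
make_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.integer(y)
  k_eff <- max(2L, min(k, sum(y == 1L), sum(y == 0L)))
  if (k_eff < k) {
    message(sprintf("reducing folds from %d to %d (smallest class has %d cases)",
                    k, k_eff, min(sum(y == 1L), sum(y == 0L))))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k_eff), length(idx))
    }
  })
  folds
}

# out-of-fold scores for one candidate learner over fixed folds
cv_scores <- function(x, y, folds, learner, seed = 1L, num_trees = 500L) {
  out <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (is.function(learner)) {
      out[te] <- learner(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
    } else {
      fit <- fit_classifier(learner, x[!te, , drop = FALSE], y[!te],
                            seed = derive_seed(seed, f), num_trees = num_trees)
      out[te] <- score_classifier(fit, x[te, , drop = FALSE])
    }
  }
  out
}

#' Screen feature groups for one target
#'
#' Considers each predictor variable's feature group independently: the
#' screening learner is cross-validated on that group alone, and the group
#' is kept when the pooled out-of-fold AUROC strictly exceeds the
#' threshold. Screening is specific to a (target, imputation variant) pair.
#'
#' @param m A complete (imputed) `feature_matrix`.
#' @param y Binary target over the matrix rows (0/1 or logical).
#' @param threshold Keep a group when its CV AUROC is `> threshold`
#'   (strict).
#' @param k Folds.
#' @param seed Seed for the fold assignment.
#' @param learner Screening learner: one of `"random_forest"`,
#'   `"ridge_logistic"`, `"svm_rbf"`, or a function
#'   `f(x_train, y_train, x_test) -> scores` (useful for testing).
#' @param folds Optional precomputed fold assignment.
#' @param num_trees Forest size for the screening learner; smaller than the
#'   final-model default because screening only ranks one variable's group
#'   against a fixed cut.
#' @return Character vector of kept `variable_id`s, with the per-group
#'   AUROCs as attribute `auroc`.
#' @export
screen_feature_groups <- function(m, y, threshold = 0.55, k = 5L, seed = 1L,
                                  learner = "random_forest", folds = NULL,
                                  num_trees = 100L) {
  sch <- attr(m, "schema")
  y <- as.integer(y)
  stopifnot(length(y) == nrow(m), all(y %in% c(0L, 1L)))
  if (is.null(folds)) folds <- make_folds(y, k, seed)
  groups <- unique(sch$variable_id)
  auc <- stats::setNames(rep(NA_real_, length(groups)), groups)
  for (g in groups) {
    cols <- which(sch$variable_id == g)
    s <- cv_scores(unclass(m)[, cols, drop = FALSE], y, folds, learner, seed,
                   num_trees = num_trees)
    auc[g] <- auroc(s, y)
  }
  kept <- groups[auc > threshold]
  structure(kept, auroc = auc)
}

#' Fit the relevance model for one target
#'
#' The central fitting function: given the two imputed training variants and
#' one target's binary labels, evaluates all six (imputation x classifier)
#' candidates by stratified k-fold cross-validation (one shared fold
#' assignment) on the features that survive per-variable screening under
#' the matching variant, selects the best mean CV AUROC (ties broken by the
#' fixed preference order: median before regression; penalized-linear,
#' max-margin, tree-ensemble), and refits the winner on all training cases.
#' When no feature group survives screening in either variant, the model
#' falls back to an intercept-only scorer equal to the training prevalence.
#'
#' @param median_matrix,regression_matrix The two complete training
#'   variants, aligned on cases (identical schema and dimensions).
#' @param y Binary target labels over the rows (absent cases must already be
#'   excluded).
#' @param target Item identifier (bookkeeping only).
#' @param source Label source (`"manual"` or `"gaze"`; bookkeeping only).
#' @param k Cross-validation folds.
#' @param seed Seed controlling folds and the tree ensembles.
#' @param screen_threshold Per-group screening AUROC cut (strict).
#' @param screening_learner See [screen_feature_groups()].
#' @return Object of class `relevance_fit`.
#' @export
relevance_fit <- function(median_matrix, regression_matrix, y,
                          target = "target", source = "manual",
                          k = 5L, seed = 1L, screen_threshold = 0.55,
                          screening_learner = "random_forest") {
  stopifnot(identical(dim(median_matrix), dim(regression_matrix)),
            identical(colnames(median_matrix), colnames(regression_matrix)))
  y <- as.integer(y)
  stopifnot(length(y) == nrow(median_matrix), all(y %in% c(0L, 1L)))
  variants <- list(median = median_matrix, regression = regression_matrix)
  folds <- make_folds(y, k, seed)
  # screening uses its own fold assignment so that the candidate CV scores
  # are not inflated by groups selected on the very same splits
  screen_folds <- make_folds(y, k, derive_seed(seed, 7L))

  screened <- lapply(variants, function(m) {
    screen_feature_groups(m, y, threshold = screen_threshold,
                          folds = screen_folds, seed = seed,
                          learner = screening_learner)
  })
  grid <- candidate_grid()
  grid$cv_auroc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    v <- grid$imputation[i]
    cols <- screened_columns(variants[[v]], screened[[v]])
    s <- cv_scores(unclass(variants[[v]])[, cols, drop = FALSE], y, folds,
                   grid$classifier[i], seed = derive_seed(seed, 100L + i))
    per_fold <- vapply(sort(unique(folds)), function(f) {
      yy <- y[folds == f]
      if (length(unique(yy)) < 2L) return(NA_real_)
      auroc(s[folds == f], yy)
    }, 0)
    grid$cv_auroc[i] <- mean(per_fold, na.rm = TRUE)
  }
  best <- which(grid$cv_auroc == max(grid$cv_auroc))[1L]
  v <- grid$imputation[best]
  cols <- screened_columns(variants[[v]], screened[[v]])
  fallback <- length(cols) == 0L
  final <- fit_classifier(grid$classifier[best],
                          unclass(variants[[v]])[, cols, drop = FALSE], y,
                          seed = derive_seed(seed, 999L))
  structure(list(
    target = target, source = source,
    candidates = grid,
    winner = grid[best, c("imputation", "classifier")],
    cv_auroc = grid$cv_auroc[best],
    screened_groups = screened,
    model = final,
    fallback = fallback,
    n_positive = sum(y == 1L), n_negative = sum(y == 0L),
    k = length(unique(folds)), seed = seed
  ), class = "relevance_fit")
}

screened_columns <- function(m, groups) {
  sch <- attr(m, "schema")
  colnames(m)[sch$variable_id %in% groups]
}

#' Predict relevance scores for new cases
#'
#' @param object A [relevance_fit()].
#' @param newdata A complete `feature_matrix` imputed under the winning
#'   variant's scheme (see [apply_imputation()]).
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`; higher means more likely relevant.
#'   Features discarded at screening do not influence the score.
#' @export
predict.relevance_fit <- function(object, newdata, ...) {
  score_classifier(object$model, unclass(newdata))
}

#' @export
print.relevance_fit <- function(x, ...) {
  cat(sprintf("Relevance model for '%s' (%s labels)\n", x$target, x$source))
  if (x$fallback) {
    cat("  intercept-only fallback (no feature group survived screening)\n")
    cat(sprintf("  score = training prevalence = %.3f\n", x$model$prevalence))
  } else {
    cat(sprintf("  winner: %s imputation + %s (CV AUROC %.3f, %d-fold)\n",
                x$winner$imputation, x$winner$classifier, x$cv_auroc, x$k))
    cat(sprintf("  screened groups kept: %d (median) / %d (regression)\n",
                length(x$screened_groups$median),
                length(x$screened_groups$regression)))
  }
  cat(sprintf("  training labels: %d positive / %d negative\n",
              x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
summary.relevance_fit <- function(object, ...) {
  print(object)
  cat("  candidate CV AUROCs:\n")
  print(object$candidates, row.names = FALSE)
  invisible(object)
}

#' @export
coef.relevance_fit <- function(object, ...) {
  if (identical(object$model$classifier, "ridge_logistic")) {
    drop(as.matrix(stats::coef(object$model$fit)))
  } else {
    NULL
  }
}
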