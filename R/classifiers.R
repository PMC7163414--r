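# Internal classifier wrappers: one fit/score interface over the three
# classifier families used for per-item relevance models. Scores are always
# oriented so that higher means more likely relevant, and mapped into [0, 1]
# (AUROC is rank-based, so the monotone mapping is inconsequential).

CLASSIFIERS <- c("ridge_logistic", "svm_rbf", "random_forest")
IMPUTATIONS <- c("median", "regression")

#' The six candidate configurations
#'
#' Every target's model is selected among the cross of two imputation
#' variants and three classifiers: L2-penalized logistic regression, an
#' RBF-kernel support vector classifier, and a random forest. Order defines
#' the tie-break preference.
#' @return Data frame with columns `imputation`, `classifier`.
#' @export
candidate_grid <- function() {
  g <- expand.grid(classifier = CLASSIFIERS, imputation = IMPUTATIONS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("imputation", "classifier")]
  rownames(g) <- NULL
  g
}

fit_classifier <- function(classifier, x, y, seed = 1L, num_trees = 500L) {
  stopifnot(classifier %in% CLASSIFIERS, is.logical(y) || all(y %in% c(0, 1)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    return(structure(list(classifier = "prevalence", prevalence = mean(y)),
                     class = "gz_classifier"))
  }
  if (is.null(dim(x)) || ncol(x) == 0L) {
    return(structure(list(classifier = "prevalence", prevalence = mean(y)),
                     class = "gz_classifier"))
  }
  fit <- switch(classifier,
    ridge_logistic = {
      xx <- if (ncol(x) < 2L) cbind(x, .pad = 0) else x
      # small positive classes are routine near the >3-positives cut
      suppressWarnings(
        glmnet::glmnet(xx, factor(y, levels = c(0L, 1L)), family = "binomial",
                       alpha = 0, lambda = 1 / nrow(xx), standardize = TRUE))
    },
    svm_rbf = {
      suppressWarnings(
        e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                   cost = 1, scale = apply(x, 2L, stats::sd) > 0))
    },
    random_forest = {
      ranger::ranger(y = factor(y, levels = c(0L, 1L)),
                     x = as.data.frame(x), probability = TRUE,
                     num.trees = num_trees, seed = seed, num.threads = 1L)
    })
  obj <- structure(list(classifier = classifier, fit = fit,
                        features = colnames(x), flip = FALSE),
                   class = "gz_classifier")
  # orient the SVM decision values empirically on the training data
  if (classifier == "svm_rbf") {
    s <- raw_scores(obj, x)
    if (auroc(s, y) < 0.5) obj$flip <- TRUE
  }
  obj
}

raw_scores <- function(obj, x) {
  switch(obj$classifier,
    prevalence = rep(obj$prevalence, nrow(x)),
    ridge_logistic = {
      xx <- if (length(obj$features) < 2L) cbind(x, .pad = 0) else x
      drop(stats::predict(obj$fit, newx = xx, type = "response"))
    },
    svm_rbf = {
      p <- stats::predict(obj$fit, x, decision.values = TRUE)
      dv <- drop(attr(p, "decision.values"))
      sgn <- if (grepl("^1", colnames(attr(p, "decision.values"))[1L])) 1 else -1
      stats::plogis(sgn * dv)
    },
    random_forest = {
      stats::predict(obj$fit, data = as.data.frame(x),
                     num.threads = 1L)$predictions[, "1"]
    })
}

score_classifier <- function(obj, x) {
  stopifnot(inherits(obj, "gz_classifier"))
  if (obj$classifier != "prevalence") {
    missing <- setdiff(obj$features, colnames(x))
    if (length(missing) > 0L) {
      stopf("feature schema mismatch; missing: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    }
    x <- x[, obj$features, drop = FALSE]
  }
  s <- raw_scores(obj, x)
  if (isTRUE(obj$flip)) s <- 1 - s
  unname(s)
}
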