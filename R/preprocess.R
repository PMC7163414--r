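# Preprocessing of the training feature matrix, in fixed order:
# constant-feature removal, duplicate-feature merging, then one of two
# imputation schemes (median/mode, or regression). Observed cells are never
# altered; the two imputed variants share identical schema and dimensions.

#' Remove features constant across all cases
#'
#' A feature is removed when it has a single distinct observed value (an
#' all-missing column counts as constant). The removal log is stored in
#' attribute `removed_features`.
#'
#' @param m A `feature_matrix`.
#' @return The pruned `feature_matrix`.
#' @export
remove_constant_features <- function(m) {
  n_distinct <- apply(m, 2L, function(col) length(unique(col[!is.na(col)])))
  keep <- n_distinct > 1L
  out <- subset_features(m, which(keep))
  attr(out, "removed_features") <- colnames(m)[!keep]
  out
}

#' Merge duplicate features
#'
#' Features identical in every case (including matching missingness) are
#' collapsed to one; within a duplicate class the canonically-first feature
#' (schema order) is retained. This routinely merges the ever-measured flags
#' of laboratory tests ordered together as a panel. The classes are stored
#' in attribute `duplicate_classes`.
#'
#' @param m A `feature_matrix`.
#' @return The deduplicated `feature_matrix`.
#' @export
deduplicate_features <- function(m) {
  key <- apply(unclass(m), 2L, function(col) paste(col, collapse = "\r"))
  first <- !duplicated(key)               # NA patterns compare equal
  classes <- split(colnames(m), factor(key, levels = key[first]))
  names(classes) <- colnames(m)[first]
  classes <- Filter(function(cl) length(cl) > 1L, classes)
  out <- subset_features(m, which(first))
  attr(out, "duplicate_classes") <- classes
  out
}

#' Median/mode imputation
#'
#' Missing numeric cells are filled with the column median over observed
#' values; nominal (integer-coded) cells with the column mode, ties broken
#' toward the smallest value. Columns with no observed values are filled
#' with 0 and logged. The fitted fill values are stored in attribute
#' `imputation` so the same fills can be applied to evaluation data.
#'
#' @param m A `feature_matrix`.
#' @return A complete `feature_matrix` (variant tag `median`).
#' @export
impute_median_mode <- function(m) {
  sch <- attr(m, "schema")
  fills <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j][!is.na(m[, j])]
    if (length(col) == 0L) return(0)
    if (sch$type[j] == "nominal") {
      tb <- table(col)
      as.numeric(names(tb)[which.max(tb)])   # table is sorted; first max = smallest
    } else {
      stats::median(col)
    }
  }, 0)
  names(fills) <- colnames(m)
  out <- apply_imputation(m, list(method = "median", fills = fills))
  out
}

#' Regression imputation
#'
#' Each incomplete column is imputed from a model fitted on the cases where
#' it is observed, with all other columns (median/mode-pre-filled) as
#' predictors: linear regression for continuous features, logistic
#' regression for binary nominal features. Degenerate fits (constant
#' outcome, singular design, non-binary nominal) fall back to the
#' median/mode fill and are logged in attribute `imputation$fallbacks`.
#'
#' @param m A `feature_matrix`.
#' @return A complete `feature_matrix` (variant tag `regression`).
#' @export
impute_regression <- function(m) {
  sch <- attr(m, "schema")
  base <- impute_median_mode(m)
  fills <- attr(base, "imputation")$fills
  X <- unclass(base)
  models <- list()
  fallbacks <- character(0)
  out <- unclass(m)
  for (j in which(colSums(is.na(m)) > 0L)) {
    obs <- !is.na(m[, j])
    y <- m[obs, j]
    nm <- colnames(m)[j]
    fallback <- TRUE
    if (length(unique(y)) >= 2L && sum(obs) >= 3L) {
      Z <- X[, -j, drop = FALSE]
      if (sch$type[j] == "nominal") {
        uy <- sort(unique(y))
        if (length(uy) == 2L) {
          yy <- as.numeric(y == uy[2L])
          fit <- tryCatch(
            suppressWarnings(stats::glm.fit(cbind(1, Z[obs, , drop = FALSE]), yy,
                                            family = stats::binomial())),
            error = function(e) NULL)
          if (!is.null(fit)) {
            co <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
            pr <- stats::plogis(drop(cbind(1, Z[!obs, , drop = FALSE]) %*% co))
            out[!obs, j] <- ifelse(pr >= 0.5, uy[2L], uy[1L])
            models[[nm]] <- list(type = "logistic", coef = co, levels = uy)
            fallback <- FALSE
          }
        }
      } else {
        fit <- tryCatch(stats::lm.fit(cbind(1, Z[obs, , drop = FALSE]), y),
                        error = function(e) NULL)
        if (!is.null(fit) && all(is.finite(fit$coefficients) |
                                 is.na(fit$coefficients))) {
          co <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          out[!obs, j] <- drop(cbind(1, Z[!obs, , drop = FALSE]) %*% co)
          models[[nm]] <- list(type = "linear", coef = co)
          fallback <- FALSE
        }
      }
    }
    if (fallback) {
      out[!obs, j] <- fills[[nm]]
      fallbacks <- c(fallbacks, nm)
    }
  }
  structure(out, schema = sch, codebooks = attr(m, "codebooks"),
            imputation = list(method = "regression", fills = fills,
                              models = models, fallbacks = fallbacks),
            class = "feature_matrix")
}

#' Apply a fitted imputation to (new) data
#'
#' Fills missing cells of `m` using an imputation fitted on training data,
#' so evaluation cases are imputed under the training distribution.
#'
#' @param m A `feature_matrix` with the same columns as the training matrix.
#' @param imputation The `imputation` attribute of an imputed training
#'   matrix (or a `list(method, fills, models)`).
#' @return A complete `feature_matrix`.
#' @export
apply_imputation <- function(m, imputation) {
  fills <- imputation$fills
  if (!all(colnames(m) %in% names(fills))) {
    stopf("imputation was fitted on a different feature set")
  }
  out <- unclass(m)
  if (identical(imputation$method, "regression")) {
    pre <- out
    for (j in seq_len(ncol(pre))) {
      pre[is.na(pre[, j]), j] <- fills[[colnames(pre)[j]]]
    }
    for (j in which(colSums(is.na(out)) > 0L)) {
      nm <- colnames(out)[j]
      mod <- imputation$models[[nm]]
      miss <- is.na(out[, j])
      if (is.null(mod)) {
        out[miss, j] <- fills[[nm]]
      } else {
        Z <- pre[miss, setdiff(colnames(pre), nm), drop = FALSE]
        eta <- drop(cbind(1, Z) %*% mod$coef)
        out[miss, j] <- if (mod$type == "logistic") {
          ifelse(stats::plogis(eta) >= 0.5, mod$levels[2L], mod$levels[1L])
        } else eta
      }
    }
  } else {
    for (j in which(colSums(is.na(out)) > 0L)) {
      out[is.na(out[, j]), j] <- fills[[colnames(out)[j]]]
    }
  }
  structure(out, schema = attr(m, "schema"), codebooks = attr(m, "codebooks"),
            imputation = imputation, class = "feature_matrix")
}

#' Full preprocessing stack
#'
#' Constants, then duplicates, then both imputations, producing the two
#' training variants ("two distinct data sets") that downstream model
#' selection chooses between.
#'
#' @param m A raw training `feature_matrix`.
#' @return List with `median` and `regression` complete matrices (identical
#'   schema and dimensions) and the removal/merge logs.
#' @export
preprocess_features <- function(m) {
  m1 <- remove_constant_features(m)
  m2 <- deduplicate_features(m1)
  med <- impute_median_mode(m2)
  reg <- impute_regression(m2)
  stopifnot(identical(dim(med), dim(reg)),
            identical(colnames(med), colnames(reg)))
  list(median = med, regression = reg,
       removed_constant = attr(m1, "removed_features"),
       duplicate_classes = attr(m2, "duplicate_classes"))
}
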