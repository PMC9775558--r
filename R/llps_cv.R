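#' Train a composite LLPS predictor by cross-validated AUC maximisation
#'
#' The main fitting function of the package. Given per-sequence features and
#' positive/negative labels it runs [cross_validate()] — `M` random `k`-fold
#' partitions, with the free weights of the chosen composite score fitted on
#' each training set by Nelder-Mead maximisation of the AUC — and returns a
#' fitted-model object. The consensus weights (the mean of the per-fold
#' optima when they are compatible with normality, otherwise the median) are
#' used by `coef`, `predict` and `plot`.
#'
#' @inheritParams cross_validate
#' @return An object of class `llps_cv` with components `score`, `k`, `M`,
#'   `folds`, `summary`, `weights` (consensus), `skipped`, plus the training
#'   `features` and `labels`.
#' @seealso [predict.llps_cv()], [plot.llps_cv()]
#' @examples
#' \donttest{
#' sim <- generate_feature_dataset(n = 300, seed = 7)
#' fit <- llps_train(sim$features, sim$labels, score = "s1", k = 5, M = 2,
#'                   seed = 7)
#' fit
#' coef(fit)
#' }
#' @export
llps_train <- function(features, labels, score = "s4", k = 5L, M = 25L,
                       seed = NULL, restarts = 5L, stratify = FALSE,
                       maxit = 500L, reltol = 1e-8) {
  cv <- cross_validate(features, labels, score = score, k = k, M = M,
                       seed = seed, restarts = restarts, stratify = stratify,
                       maxit = maxit, reltol = reltol)
  free <- SCORE_SPECS[[score]]$free
  weights <- stats::setNames(
    cv$summary$value[match(free, cv$summary$quantity)], free)
  structure(list(score = score, k = as.integer(k), M = as.integer(M),
                 seed = seed, folds = cv$folds, summary = cv$summary,
                 weights = weights, skipped = cv$skipped,
                 features = features, labels = as_binary_labels(labels),
                 call = match.call()),
            class = "llps_cv")
}

#' @export
print.llps_cv <- function(x, ...) {
  ta <- x$summary[x$summary$quantity == "test_auc", ]
  tm <- x$summary[x$summary$quantity == "test_mcc", ]
  cat(sprintf("Cross-validated composite LLPS score '%s' (k = %d, M = %d, %d folds)\n",
              x$score, x$k, x$M, nrow(x$folds)))
  cat(sprintf("  test AUC %.3f +/- %.3f   test max-MCC %.3f +/- %.3f\n",
              ta$value, ta$sd, tm$value, tm$sd))
  cat("  consensus weights: ",
      paste(sprintf("%s = %.4g", names(x$weights), x$weights), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.llps_cv <- function(object, ...) {
  out <- object$summary
  attr(out, "score") <- object$score
  class(out) <- c("summary.llps_cv", class(out))
  out
}

#' @export
print.summary.llps_cv <- function(x, ...) {
  cat(sprintf("Fold summary for score '%s' (value = mean if KS-normal, else median):\n",
              attr(x, "score")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.llps_cv <- function(object, ...) object$weights

#' Predict composite scores for new sequences
#'
#' Applies the fitted consensus weights to a new feature table. Higher scores
#' predict phase separation; thresholding is left to the caller (see
#' [max_mcc()] for an MCC-optimal threshold on labelled data).
#'
#' @param object an `llps_cv` fit from [llps_train()].
#' @param newdata feature data frame (see [assemble_features()]); defaults to
#'   the training features.
#' @param ... unused.
#' @return Numeric vector of composite scores.
#' @export
predict.llps_cv <- function(object, newdata = NULL, ...) {
  composite_score(object$score, newdata %||% object$features, object$weights)
}

#' ROC curve of a fitted composite score
#'
#' Plots the ROC curve of the consensus-weight score on the training data,
#' with the chance diagonal and the training-data AUC in the legend.
#'
#' @param x an `llps_cv` fit.
#' @param ... passed to [graphics::plot()].
#' @return The [roc_curve()] data frame, invisibly.
#' @export
plot.llps_cv <- function(x, ...) {
  s <- predict(x)
  r <- roc_curve(s, x$labels)
  a <- auc(s, x$labels)
  plot(r$fpr, r$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 2, col = "grey50")
  legend("bottomright", bty = "n",
         legend = sprintf("%s, AUC = %.3f", x$score, a))
  invisible(r)
}
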