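# weight training: k-fold cross-validation with Nelder-Mead AUC maximisation

#' Random k-fold partition
#'
#' Randomly partitions a set of items into `k` disjoint folds whose sizes
#' differ by at most one. The partition is over the union of the positive and
#' negative sets and is unstratified by default (an optional stratified mode
#' keeps the class ratio approximately constant across folds).
#'
#' @param ids vector of item identifiers (or indices).
#' @param k number of folds (>= 2).
#' @param seed optional RNG seed for a reproducible partition.
#' @param stratify optional label vector aligned with `ids`; if supplied, each
#'   class is partitioned separately.
#' @return A list of `k` vectors of ids, disjoint with union `ids`.
#' @export
kfold_partition <- function(ids, k, seed = NULL, stratify = NULL) {
  n <- length(ids)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of items")
  with_seed(seed, {
    if (is.null(stratify)) {
      fold_of <- sample(rep_len(seq_len(k), n))
    } else {
      stopifnot(length(stratify) == n)
      fold_of <- integer(n)
      for (cl in unique(stratify)) {
        idx <- which(stratify == cl)
        fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    lapply(seq_len(k), function(f) ids[fold_of == f])
  })
}

# random multi-start initialisations scaled so each weighted term is
# commensurate with the score's fixed unit-weight term
weight_scales <- function(features, score) {
  spec <- SCORE_SPECS[[score]]
  base <- if (spec$uses_P) features$P else features$E_over_N
  sb <- sd(base); if (!is.finite(sb) || sb == 0) sb <- 1
  vapply(spec$free, function(w) {
    col <- switch(w, alpha = "E_over_N", beta = "lnS1", gamma = "lnlp")
    sf <- sd(features[[col]])
    if (!is.finite(sf) || sf == 0) 1 else sb / sf
  }, numeric(1))
}

#' Optimise the weights of a composite score by AUC maximisation
#'
#' Maximises the training-set AUC of [composite_score()] over the score's
#' free weights with the Nelder-Mead simplex. Because the empirical AUC is
#' piecewise constant in the weights, the simplex can stall on plateaus; the
#' optimiser is therefore multi-started from the zero vector plus `restarts`
#' random initialisations whose scale matches the spread of the fixed-weight
#' term, and the best restart is returned. The reported AUC is always the
#' exact rank AUC.
#'
#' @param features feature data frame (see [assemble_features()]).
#' @param labels class labels aligned with the rows of `features`.
#' @param score score name, see [score_weight_names()].
#' @param restarts number of random restarts in addition to the zero start.
#' @param seed optional RNG seed (restart draws only).
#' @param maxit,reltol Nelder-Mead control parameters.
#' @return A list with `weights` (named vector), `train_auc`, and `start_auc`
#'   (the AUC of the all-zero weight vector, a monotone-improvement floor).
#' @export
optimize_weights <- function(features, labels, score, restarts = 5L,
                             seed = NULL, maxit = 500L, reltol = 1e-8) {
  score <- match.arg(score, names(SCORE_SPECS))
  lab <- as_binary_labels(labels)
  if (length(lab) != nrow(features)) stop("labels do not match feature rows")
  if (!any(lab) || all(lab)) stop("both classes must be present in the training set")
  free <- SCORE_SPECS[[score]]$free
  obj <- function(w) {
    -auc_fast(composite_score(score, features, stats::setNames(w, free)), lab)
  }
  scales <- weight_scales(features, score)
  starts <- with_seed(seed, {
    c(list(rep(0, length(free))),
      lapply(seq_len(restarts), function(i) rnorm(length(free)) * scales))
  })
  best <- NULL
  for (w0 in starts) {
    fit <- tryCatch(
      suppressWarnings(optim(w0, obj, method = "Nelder-Mead",
                             control = list(maxit = maxit, reltol = reltol))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed on all restarts")
  list(weights = stats::setNames(best$par, free),
       train_auc = -best$value,
       start_auc = -obj(rep(0, length(free))))
}

#' k-fold cross-validation of a composite score
#'
#' Repeats `M` random k-fold partitions of the data; within each realisation
#' every fold serves once as the test set, the weights are fitted by
#' [optimize_weights()] on the union of the other `k - 1` folds, and the test
#' fold's AUC and maximum MCC are recorded. Folds whose test or training part
#' contains a single class are skipped with a warning. The summary reports,
#' for every fitted weight and performance measure, the mean, median and
#' standard deviation across the `k * M` folds plus a KS normality p-value;
#' the `value` column is the mean when the KS p-value exceeds 0.05 and the
#' median otherwise.
#'
#' @inheritParams optimize_weights
#' @param k number of folds (default 5).
#' @param M number of partition realisations (default 25).
#' @param seed RNG seed governing partitions and optimiser restarts.
#' @param stratify logical; stratify folds by label (off by default).
#' @return A list with `folds` (one row per realisation x fold: weights,
#'   `train_auc`, `test_auc`, `test_mcc`), `summary` (the statistic table) and
#'   `skipped` (count of single-class folds).
#' @export
cross_validate <- function(features, labels, score = "s4", k = 5L, M = 25L,
                           seed = NULL, restarts = 5L, stratify = FALSE,
                           maxit = 500L, reltol = 1e-8) {
  score <- match.arg(score, names(SCORE_SPECS))
  lab <- as_binary_labels(labels)
  n <- nrow(features)
  if (length(lab) != n) stop("labels do not match feature rows")
  if (M < 1L) stop("M must be >= 1")
  free <- SCORE_SPECS[[score]]$free
  seeds <- with_seed(seed, matrix(sample.int(2^30, 2L * M), nrow = M))
  rows <- list(); skipped <- 0L
  for (r in seq_len(M)) {
    folds <- kfold_partition(seq_len(n), k, seed = seeds[r, 1L],
                             stratify = if (stratify) lab else NULL)
    for (f in seq_len(k)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      if (length(unique(lab[train])) < 2L || length(unique(lab[test])) < 2L) {
        warning("skipping single-class fold (realisation ", r, ", fold ", f, ")")
        skipped <- skipped + 1L
        next
      }
      fit <- optimize_weights(features[train, , drop = FALSE], lab[train],
                              score, restarts = restarts,
                              seed = seeds[r, 2L] + f, maxit = maxit,
                              reltol = reltol)
      s_test <- composite_score(score, features[test, , drop = FALSE], fit$weights)
      row <- c(realisation = r, fold = f, fit$weights,
               train_auc = fit$train_auc,
               test_auc = auc_fast(s_test, lab[test]),
               test_mcc = max_mcc(s_test, lab[test])$mcc)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("no usable folds")
  folds_df <- as.data.frame(do.call(rbind, rows))
  list(folds = folds_df,
       summary = summarize_folds(folds_df, c(free, "train_auc", "test_auc", "test_mcc")),
       skipped = skipped)
}

# mean-or-median summary table over fold results, with KS normality flags
summarize_folds <- function(folds_df, cols) {
  rows <- lapply(cols, function(cl) {
    x <- folds_df[[cl]]
    ks <- tryCatch(ks_normality(x), error = function(e) NA_real_)
    normal <- !is.na(ks) && ks > 0.05
    data.frame(quantity = cl, n = length(x), mean = mean(x),
               median = median(x), sd = sd(x), ks_p = ks, normal = normal,
               value = if (normal) mean(x) else median(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-fold evaluation of a fixed (pre-trained) score
#'
#' Evaluates scores that involve no fitting (e.g. PScore alone) on each test
#' fold of a partition, for comparison with cross-validated composite scores.
#'
#' @param scores numeric scores for all items.
#' @param labels class labels aligned with `scores`.
#' @param folds list of index vectors (e.g. from [kfold_partition()]).
#' @return A data frame with one row per usable fold: `fold`, `test_auc`,
#'   `test_mcc`. Single-class folds are skipped with a warning.
#' @export
evaluate_fixed_score <- function(scores, labels, folds) {
  lab <- as_binary_labels(labels)
  rows <- list()
  for (f in seq_along(folds)) {
    idx <- folds[[f]]
    if (length(unique(lab[idx])) < 2L) {
      warning("skipping single-class fold ", f)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(fold = f, test_auc = auc_fast(scores[idx], lab[idx]),
                 test_mcc = max_mcc(scores[idx], lab[idx])$mcc)
  }
  if (!length(rows)) stop("no usable folds")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
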