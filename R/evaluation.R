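# binary-classifier evaluation: confusion counts, ROC/AUC, MCC

#' Confusion counts at a decision threshold
#'
#' A sequence is predicted positive iff its score is greater than or equal to
#' the threshold (the tie convention; ROC construction steps through distinct
#' score values, so the convention never changes the AUC).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels class labels aligned with `scores`: logical, 0/1, or
#'   `"positive"`/`"negative"`.
#' @param t threshold.
#' @return Named integer vector with elements `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  if (!length(scores)) stop("empty input")
  lab <- as_binary_labels(labels)
  if (length(lab) != length(scores)) stop("scores and labels lengths differ")
  pred <- scores >= t
  c(TP = sum(pred & lab), FN = sum(!pred & lab),
    TN = sum(!pred & !lab), FP = sum(pred & !lab))
}

#' Empirical ROC curve
#'
#' Steps the threshold through `+Inf` and every distinct score value in
#' decreasing order, recording the false-positive rate, true-positive rate and
#' the Matthews correlation coefficient at each point. The curve starts at
#' `(0, 0)` and ends at `(1, 1)`.
#'
#' @inheritParams confusion_at_threshold
#' @return A data frame with columns `threshold`, `fpr`, `tpr`, `mcc`.
#' @export
roc_curve <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (length(lab) != length(scores)) stop("scores and labels lengths differ")
  P <- sum(lab); N <- sum(!lab)
  if (P == 0L || N == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- lab[o]
  # index of the last element of each tie group = cumulative counts at that threshold
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  thr <- c(Inf, s[last])
  tp <- c(0L, tp); fp <- c(0L, fp)
  data.frame(threshold = thr,
             fpr = fp / N, tpr = tp / P,
             mcc = mcc_from_counts(tp, fp, N - fp, P - tp))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC curve of [roc_curve()]. With the
#' step construction through distinct scores this equals the rank statistic
#' `P(score_pos > score_neg) + 0.5 * P(tie)`.
#'
#' @inheritParams confusion_at_threshold
#' @return The AUC, in `[0, 1]`.
#' @examples
#' auc(c(1, 2, 3), c(FALSE, TRUE, TRUE))
#' @export
auc <- function(scores, labels) {
  r <- roc_curve(scores, labels)
  sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-nrow(r)]) / 2)
}

# fast AUC on pre-coerced logical labels, used inside the optimiser loop;
# rank formulation, identical to the trapezoid of the step ROC
auc_fast <- function(scores, lab) {
  P <- sum(lab); N <- length(lab) - P
  (sum(rank(scores)[lab]) - P * (P + 1) / 2) / (P * N)
}

# vectorised MCC with the 0/0 -> 0 convention; doubles avoid integer overflow
mcc_from_counts <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- ifelse(den > 0, (tp * tn - fp * fn) / sqrt(den), 0)
  as.numeric(out)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that the value is 0 whenever a denominator factor vanishes
#' (consistent with the bottom-left `TP = FP = 0` and top-right
#' `TN = FN = 0` corners of the ROC curve).
#'
#' @param counts named vector or list with elements `TP`, `FP`, `TN`, `FN`,
#'   e.g. from [confusion_at_threshold()].
#' @return The MCC, in `[-1, 1]`.
#' @examples
#' mcc(c(TP = 3, FP = 1, TN = 4, FN = 2)) # 10 / sqrt(600)
#' @export
mcc <- function(counts) {
  counts <- unlist(counts)
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(counts))) stop("counts must name TP, FP, TN, FN")
  if (any(counts[need] < 0)) stop("negative counts")
  mcc_from_counts(counts[["TP"]], counts[["FP"]], counts[["TN"]], counts[["FN"]])
}

#' Maximum MCC over classification thresholds
#'
#' Evaluates the MCC at every threshold midway between consecutive distinct
#' scores, plus the `-Inf` and `+Inf` corners, and returns the maximum. Ties
#' are broken deterministically towards the highest threshold attaining the
#' maximum.
#'
#' @inheritParams confusion_at_threshold
#' @return A list with `mcc` and `threshold`.
#' @export
max_mcc <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (length(lab) != length(scores)) stop("scores and labels lengths differ")
  P <- sum(lab); N <- sum(!lab)
  if (P == 0L || N == 0L) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- lab[o]
  npos <- vapply(thr, function(t) sum(s >= t & l), numeric(1))
  nfp <- vapply(thr, function(t) sum(s >= t & !l), numeric(1))
  m <- mcc_from_counts(npos, nfp, N - nfp, P - npos)
  best <- max(m)
  i <- max(which(m == best)) # thresholds ascend, so this is the highest
  list(mcc = best, threshold = thr[i])
}

#' MCC under growing negative-set size at fixed rates
#'
#' Illustrates the size-dilution property of the MCC: with the sensitivity
#' (`tpr`), false-alarm rate (`fpr`) and positive-set size `P` held fixed, the
#' MCC decreases towards 0 as the negative-set size grows.
#'
#' @param fpr,tpr fixed false-positive and true-positive rates in `(0, 1)`.
#' @param P positive-set size.
#' @param N_sizes numeric vector of negative-set sizes.
#' @return Numeric vector of MCC values, one per element of `N_sizes`.
#' @export
mcc_dilution_check <- function(fpr, tpr, P, N_sizes) {
  stopifnot(fpr > 0, fpr < 1, tpr > 0, tpr < 1, P > 0, all(N_sizes > 0))
  vapply(N_sizes, function(N) {
    mcc_from_counts(tpr * P, fpr * N, (1 - fpr) * N, (1 - tpr) * P)
  }, numeric(1))
}

#' One-way ANOVA across groups of AUC values
#'
#' Compares groups of AUC values (e.g. cross-validation test AUCs of
#' different scoring functions) with a one-way fixed-effects ANOVA and reports
#' the F statistic, p-value and the effect size
#' `eta^2 = SS_between / SS_total`.
#'
#' @param groups a (preferably named) list of numeric vectors, each with at
#'   least 2 values.
#' @return A list with `F`, `p`, `eta2`, `df_between`, `df_within`.
#' @export
compare_auc_distributions <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop("each group needs >= 2 values")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  if (var(value) == 0) stop("degenerate groups: all values identical")
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  # the perfect-fit warning fires in the degenerate all-between-variance case,
  # where the F = Inf / p = 0 / eta2 = 1 limit is the intended answer
  tab <- suppressWarnings(anova(lm(value ~ g)))
  ssb <- tab$`Sum Sq`[1L]; ssw <- tab$`Sum Sq`[2L]
  dfb <- tab$Df[1L]; dfw <- tab$Df[2L]
  Fv <- if (ssw == 0) Inf else (ssb / dfb) / (ssw / dfw)
  p <- if (is.finite(Fv)) pf(Fv, dfb, dfw, lower.tail = FALSE) else 0
  list(F = Fv, p = p, eta2 = ssb / (ssb + ssw),
       df_between = dfb, df_within = dfw)
}

#' Kolmogorov-Smirnov normality check
#'
#' KS test of the sample against a normal distribution with the sample mean
#' and standard deviation. Because the parameters are estimated from the same
#' sample, the p-value is conservative in the Lilliefors sense (the plain KS
#' null distribution is used); this matches the common practice of reading
#' large p-values as "no evidence against normality".
#'
#' @param values numeric vector, length >= 8, non-constant.
#' @return The KS p-value.
#' @export
ks_normality <- function(values) {
  if (length(values) < 8L) stop("need at least 8 values")
  if (sd(values) == 0) stop("constant input")
  suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))$p.value
}
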