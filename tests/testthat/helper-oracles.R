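# shared fixtures and independent oracles for the test suite

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

make_table <- function(mat, orientation) {
  dimnames(mat) <- list(AA, AA)
  energy_table(mat, orientation)
}

zero_tables <- function() {
  list(parallel = make_table(matrix(0, 20, 20), "parallel"),
       antiparallel = make_table(matrix(0, 20, 20), "antiparallel"))
}

random_seq <- function(N) paste(sample(AA, N, replace = TRUE), collapse = "")

# rank-statistic AUC: P(score_pos > score_neg) + 0.5 P(tie), by full pairwise
# comparison — independent of the package's trapezoidal ROC integration
rank_auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive threshold-sweep maximum MCC, via confusion_at_threshold only
sweep_max_mcc_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- c(-Inf, u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  max(vapply(thr, function(t) mcc(confusion_at_threshold(scores, labels, t)),
             numeric(1)))
}

# minimum-sum contiguous segment of length >= min_lp, quadratic brute force
min_sum_segment_oracle <- function(x, min_lp) {
  best <- Inf
  for (i in seq_along(x)) {
    for (j in seq(i + min_lp - 1L, length(x))) {
      if (j > length(x)) break
      best <- min(best, sum(x[i:j]))
    }
  }
  best
}

# write a canonical-format energy table file for a plain matrix
write_table_file <- function(mat, path) {
  lines <- c(paste(AA, collapse = " "),
             vapply(seq_len(20), function(i) {
               paste(AA[i], paste(format(mat[i, ], digits = 17), collapse = " "))
             }, ""))
  writeLines(lines, path)
  path
}
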