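# composite LLPS scoring: feature assembly and the six linear scores

# which free weights each score uses; E/N enters s0/s00 with a fixed unit
# coefficient, PScore enters s1-s4 with a fixed unit coefficient (this fixes
# the overall scale, making trained weights comparable across folds)
SCORE_SPECS <- list(
  s0  = list(free = "beta",                        uses_P = FALSE, fixed_EN = TRUE),
  s00 = list(free = c("beta", "gamma"),            uses_P = FALSE, fixed_EN = TRUE),
  s1  = list(free = "alpha",                       uses_P = TRUE,  fixed_EN = FALSE),
  s2  = list(free = "beta",                        uses_P = TRUE,  fixed_EN = FALSE),
  s3  = list(free = c("alpha", "beta"),            uses_P = TRUE,  fixed_EN = FALSE),
  s4  = list(free = c("alpha", "beta", "gamma"),   uses_P = TRUE,  fixed_EN = FALSE)
)

#' Names of the free weights of a composite score
#'
#' @param name one of `"s0"`, `"s00"`, `"s1"`, `"s2"`, `"s3"`, `"s4"`.
#' @return Character vector of weight names (a subset of `alpha`, `beta`,
#'   `gamma`). For `s0`/`s00` the returned `beta`/`gamma` play the role of the
#'   tilded weights multiplying `ln(S+1)` and `ln(lp)` next to a unit-weight
#'   `E/N` term.
#' @export
score_weight_names <- function(name) {
  spec <- SCORE_SPECS[[match.arg(name, names(SCORE_SPECS))]]
  spec$free
}

#' Assemble the feature vector of one scanned sequence
#'
#' Derives the predictors entering the composite scores from a pairing
#' summary and an externally computed PScore: the energy density `E/N`,
#' `ln(S+1)`, `ln(lp)`, and the fractional position `f` of the best pairing's
#' first stretch along the chain.
#'
#' @param summary a `pairing_summary` from [best_pairings()].
#' @param pscore the sequence's PScore (finite number).
#' @return A one-row data frame with columns `id`, `N`, `E`, `lp`, `S`, `P`,
#'   `E_over_N`, `lnS1`, `lnlp`, `f`.
#' @export
compute_features <- function(summary, pscore) {
  stopifnot(inherits(summary, "pairing_summary"))
  if (!is.numeric(pscore) || length(pscore) != 1L || !is.finite(pscore))
    stop("pscore must be a single finite number")
  if (summary$lp < 1L) stop("invariant violation: lp < 1")
  if (summary$S < 0) stop("invariant violation: S < 0")
  data.frame(id = summary$id %||% NA_character_,
             N = summary$N, E = summary$E, lp = summary$lp, S = summary$S,
             P = pscore,
             E_over_N = summary$E / summary$N,
             lnS1 = log(summary$S + 1),
             lnlp = log(summary$lp),
             f = fractional_position(summary$best$k, summary$best$l, summary$N),
             stringsAsFactors = FALSE)
}

#' Assemble a feature table from a batch scan and a PScore table
#'
#' Joins the [scan_sequences()] output with a per-sequence PScore table on
#' `id` and computes the derived predictors. Sequences without a PScore (for
#' example because they failed the length/alphabet compatibility filter) are
#' excluded with a message, never imputed.
#'
#' @param scan data frame from [scan_sequences()].
#' @param pscores data frame with columns `id` and `P`.
#' @return A data frame with columns `id`, `N`, `E`, `lp`, `S`, `P`,
#'   `E_over_N`, `lnS1`, `lnlp`, `f`.
#' @export
assemble_features <- function(scan, pscores) {
  stopifnot(is.data.frame(scan),
            all(c("id", "N", "E", "lp", "S", "best_k", "best_l") %in% names(scan)),
            is.data.frame(pscores), all(c("id", "P") %in% names(pscores)))
  merged <- merge(scan, pscores[, c("id", "P")], by = "id", all.x = TRUE)
  drop <- is.na(merged$P)
  if (any(drop)) {
    message("excluding ", sum(drop), " sequence(s) without a PScore")
    merged <- merged[!drop, , drop = FALSE]
  }
  data.frame(id = merged$id, N = merged$N, E = merged$E, lp = merged$lp,
             S = merged$S, P = merged$P,
             E_over_N = merged$E / merged$N,
             lnS1 = log(merged$S + 1),
             lnlp = log(merged$lp),
             f = mapply(fractional_position, merged$best_k, merged$best_l,
                        merged$N),
             stringsAsFactors = FALSE)
}

#' Evaluate a composite LLPS score
#'
#' The six scores are linear combinations of the energy density `E/N`,
#' `ln(S+1)`, `ln(lp)` and the PScore `P`:
#' \deqn{s_0 = E/N + \beta \ln(S+1)}
#' \deqn{s_{00} = E/N + \beta \ln(S+1) + \gamma \ln(l_p)}
#' \deqn{s_1 = \alpha E/N + P}
#' \deqn{s_2 = \beta \ln(S+1) + P}
#' \deqn{s_3 = \alpha E/N + \beta \ln(S+1) + P}
#' \deqn{s_4 = \alpha E/N + \beta \ln(S+1) + \gamma \ln(l_p) + P}
#' Higher scores predict phase separation.
#'
#' @param name score name, see [score_weight_names()].
#' @param fv a feature data frame with columns `E_over_N`, `lnS1`, `lnlp` and
#'   (for `s1`-`s4`) `P`, e.g. from [assemble_features()].
#' @param weights named numeric vector supplying exactly the free weights of
#'   the named score.
#' @return Numeric vector of scores, one per row of `fv`.
#' @examples
#' fv <- data.frame(E_over_N = -0.1, lnS1 = 0, lnlp = log(8), P = 5)
#' composite_score("s3", fv, c(alpha = 1, beta = 2))
#' @export
composite_score <- function(name, fv, weights) {
  name <- match.arg(name, names(SCORE_SPECS))
  spec <- SCORE_SPECS[[name]]
  if (is.list(weights)) weights <- unlist(weights)
  if (!setequal(names(weights) %||% character(0), spec$free))
    stop("configuration error: score ", name, " needs weight(s) ",
         paste(spec$free, collapse = ", "), ", got ",
         paste(names(weights) %||% "<unnamed>", collapse = ", "))
  need <- c("E_over_N", "lnS1", "lnlp", if (spec$uses_P) "P")
  miss <- setdiff(need, names(fv))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  s <- if (spec$uses_P) fv$P else fv$E_over_N
  if ("alpha" %in% spec$free) s <- s + weights[["alpha"]] * fv$E_over_N
  if ("beta" %in% spec$free) s <- s + weights[["beta"]] * fv$lnS1
  if ("gamma" %in% spec$free) s <- s + weights[["gamma"]] * fv$lnlp
  as.numeric(s)
}

#' Fractional position of a stretch along a chain
#'
#' For a stretch with 1-based inclusive endpoints `m`, `n` on a chain of `N`
#' residues, `f = min((m+n)/(2N), 1 - (m+n)/(2N))`. `f` lies in `(0, 1/2]`:
#' the closer the stretch to the chain centre, the larger `f`; stretches near
#' either terminus have `f` near 0.
#'
#' @param m,n stretch start and end (1-based inclusive, `m <= n`).
#' @param N chain length.
#' @return `f`, a number in `(0, 0.5]`.
#' @examples
#' fractional_position(10, 17, 100) # 0.135
#' @export
fractional_position <- function(m, n, N) {
  if (!(m >= 1 && n >= m && N >= n)) stop("require 1 <= m <= n <= N")
  x <- (m + n) / (2 * N)
  min(x, 1 - x)
}

#' Compare the fractional positions of two sequence sets
#'
#' Reports the mean and standard error of the mean of each set of fractional
#' positions and the two-sample statistic
#' `Z = (mean_A - mean_B) / sqrt(sem_A^2 + sem_B^2)`.
#'
#' @param fA,fB numeric vectors of fractional positions (length >= 2 each).
#' @return A list with `mean_a`, `sem_a`, `mean_b`, `sem_b`, `z`.
#' @export
compare_positional_sets <- function(fA, fB) {
  if (length(fA) < 2L || length(fB) < 2L)
    stop("sem undefined: each set needs at least 2 values")
  sem <- function(x) sd(x) / sqrt(length(x))
  sa <- sem(fA); sb <- sem(fB)
  denom <- sqrt(sa^2 + sb^2)
  if (denom == 0) stop("degenerate variance: both sets are constant")
  list(mean_a = mean(fA), sem_a = sa,
       mean_b = mean(fB), sem_b = sb,
       z = (mean(fA) - mean(fB)) / denom)
}
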