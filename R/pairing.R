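#' Construct a beta-pairing between two stretches of one sequence
#'
#' A beta-pairing hydrogen-bonds two equal-length stretches `(k, l)` and
#' `(m, n)` of the same chain, in either parallel or antiparallel orientation.
#' Pairings are unordered, so the constructor canonicalises to `m >= k`
#' (swapping the stretches if needed), which makes the register shift
#' `S = m - k = n - l` non-negative. All indices are 1-based inclusive.
#'
#' @param k,l start and end of the first stretch.
#' @param m,n start and end of the partner stretch.
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @return A list of class `beta_pairing` with fields `k`, `l`, `m`, `n`,
#'   `lp` (pairing length) and `shift`.
#' @examples
#' beta_pairing(3, 6, 1, 4, "parallel") # canonicalised so that m >= k
#' @export
beta_pairing <- function(k, l, m, n, orientation = c("parallel", "antiparallel")) {
  orientation <- match.arg(orientation)
  for (v in list(k, l, m, n))
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("stretch indices must be positive integers")
  if (l < k || n < m) stop("stretch end before start")
  if ((l - k) != (n - m)) stop("paired stretches must have equal length")
  if (m < k) { tmp <- c(k, l); k <- m; l <- n; m <- tmp[1L]; n <- tmp[2L] }
  structure(list(k = as.integer(k), l = as.integer(l),
                 m = as.integer(m), n = as.integer(n),
                 lp = as.integer(l - k + 1L), shift = as.integer(m - k),
                 orientation = orientation),
            class = "beta_pairing")
}

#' Score one beta-pairing with a residue-pair energy table
#'
#' For a parallel pairing the energy is `sum_i e(seq[k+i], seq[m+i])`; for an
#' antiparallel pairing the partner stretch is traversed in reverse,
#' `sum_i e(seq[k+i], seq[n-i])`, with `i = 0 .. lp-1`. The row of the table
#' indexes the first (lower-start) stretch's residue.
#'
#' @param seq a residue string over the 20 standard one-letter codes.
#' @param pairing a [beta_pairing()].
#' @param table an [energy_table()] whose orientation matches the pairing.
#' @return The pairing energy (dimensionless; lower = more stabilising).
#' @examples
#' tab <- generate_energy_tables(style = "zero")$parallel
#' score_pairing("VVVV", beta_pairing(1, 2, 3, 4, "parallel"), tab)
#' @export
score_pairing <- function(seq, pairing, table) {
  stopifnot(inherits(pairing, "beta_pairing"))
  table <- energy_table(unclass_table(table), attr(table, "orientation"))
  if (!identical(attr(table, "orientation"), pairing$orientation))
    stop("table orientation (", attr(table, "orientation"),
         ") does not match pairing orientation (", pairing$orientation, ")")
  code <- encode_residues(seq)
  N <- length(code)
  if (pairing$n > N || pairing$l > N)
    stop("index error: pairing extends beyond the sequence (N = ", N, ")")
  i <- seq_len(pairing$lp) - 1L
  a <- code[pairing$k + i]
  b <- if (pairing$orientation == "parallel") code[pairing$m + i] else code[pairing$n - i]
  sum(table[cbind(a, b)])
}

# strip class so [ keeps matrix semantics
unclass_table <- function(table) {
  stopifnot(inherits(table, "energy_table"))
  m <- table
  class(m) <- "matrix"
  m
}

#' Enumerate and score all beta-pairings of a sequence (brute-force reference)
#'
#' Generates exactly one canonical entry for every pairing of two equal-length
#' stretches `(k, l)` and `(m, n)` with `m >= k`, length at least `min_lp`,
#' and both stretches in bounds, in each requested orientation, and scores
#' each with [score_pairing()]'s summation. This is the quadratic-to-quartic
#' reference enumeration; the production scan in [best_pairings()] is checked
#' against it in the test suite.
#'
#' @inheritParams score_pairing
#' @param tables an [energy_table()] or `list(parallel =, antiparallel =)`;
#'   only the orientations present are enumerated.
#' @param min_lp minimum pairing length (residues), default 4.
#' @return A data frame with columns `orientation`, `k`, `l`, `m`, `n`, `lp`,
#'   `shift`, `energy`, sorted best-first by the documented tie-break (energy
#'   ascending, then longer, then smaller shift, then smaller `k`, then
#'   parallel before antiparallel).
#' @export
enumerate_pairings <- function(seq, tables, min_lp = 4L) {
  tables <- as_table_pair(tables)
  if (min_lp < 1L) stop("min_lp must be >= 1")
  code <- encode_residues(seq)
  N <- length(code)
  if (N < min_lp) stop("sequence shorter than min_lp")
  res <- list()
  for (o in names(tables)) {
    tab <- unclass_table(tables[[o]])
    ko <- integer(0); mo <- integer(0); lpo <- integer(0); en <- numeric(0)
    for (lp in min_lp:N) {
      smax <- N - lp + 1L
      i <- seq_len(lp) - 1L
      for (k in seq_len(smax)) {
        for (m in k:smax) {
          a <- code[k + i]
          b <- if (o == "parallel") code[m + i] else code[m + lp - 1L - i]
          ko <- c(ko, k); mo <- c(mo, m); lpo <- c(lpo, lp)
          en <- c(en, sum(tab[cbind(a, b)]))
        }
      }
    }
    res[[o]] <- data.frame(orientation = o, k = ko, l = ko + lpo - 1L,
                           m = mo, n = mo + lpo - 1L, lp = lpo,
                           shift = mo - ko, energy = en,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order_pairings(out), , drop = FALSE]
}

# documented tie-break order for pairing candidates
order_pairings <- function(df) {
  orank <- match(df$orientation, c("parallel", "antiparallel"))
  order(df$energy, -df$lp, df$shift, df$k, orank)
}

#' Best beta-pairings of a sequence
#'
#' Scans the full pairing landscape via its diagonal decomposition: parallel
#' pairings with a common register shift lie on one diagonal of per-position
#' energies, antiparallel pairings with a common sum of paired positions on
#' one anti-diagonal; on each diagonal the optimal pairing is the minimum-sum
#' contiguous segment of length at least `min_lp` (linear time per diagonal).
#' The `k_best` candidates are the lowest-energy diagonal optima, which
#' de-duplicates the near-identical one-residue trims that would otherwise
#' dominate a raw top-`k_best` list. The single best candidate always equals
#' the global minimum of the exhaustive enumeration.
#'
#' @inheritParams enumerate_pairings
#' @param k_best number of top pairings retained (default 5); the average
#'   register shift `S` is taken over these (or over however many diagonal
#'   optima exist, if fewer).
#' @param id optional sequence identifier stored in the summary.
#' @return An object of class `pairing_summary`: a list with `id`, `N`
#'   (chain length), `E` (lowest pairing energy), `lp` (length of that best
#'   pairing), `S` (mean register shift over the top pairings), `best` (the
#'   best pairing's coordinates) and `top_pairings` (a data frame of up to
#'   `k_best` rows, best first).
#' @examples
#' tabs <- generate_energy_tables(style = "hydrophobic")
#' best_pairings("SSSSVVVVVVSSSS", tabs, min_lp = 4)
#' @export
best_pairings <- function(seq, tables, k_best = 5L, min_lp = 4L, id = NULL) {
  tables <- as_table_pair(tables)
  if (k_best < 1L) stop("k_best must be >= 1")
  if (min_lp < 1L) stop("min_lp must be >= 1")
  code <- encode_residues(seq)
  N <- length(code)
  if (N < min_lp)
    stop("no pairing candidates: sequence length ", N, " < min_lp = ", min_lp)
  zero <- matrix(0, 20L, 20L)
  do_par <- "parallel" %in% names(tables)
  do_anti <- "antiparallel" %in% names(tables)
  cand <- .scan_diagonals(code - 1L,
                          if (do_par) unclass_table(tables$parallel) else zero,
                          if (do_anti) unclass_table(tables$antiparallel) else zero,
                          as.integer(min_lp), do_par, do_anti)
  cand$orientation <- c("parallel", "antiparallel")[cand$orient]
  cand <- cand[, c("orientation", "k", "l", "m", "n", "lp", "shift", "energy")]
  cand <- cand[order_pairings(cand), , drop = FALSE]
  top <- utils::head(cand, k_best)
  rownames(top) <- NULL
  best <- top[1L, ]
  structure(list(id = id, N = N,
                 E = best$energy, lp = best$lp,
                 S = mean(top$shift),
                 best = list(k = best$k, l = best$l, m = best$m, n = best$n,
                             shift = best$shift, orientation = best$orientation),
                 top_pairings = top),
            class = "pairing_summary")
}

#' @export
print.pairing_summary <- function(x, ...) {
  cat(sprintf("pairing_summary%s: N = %d, E = %.4g, lp = %d, S = %.3g\n",
              if (!is.null(x$id)) paste0(" [", x$id, "]") else "",
              x$N, x$E, x$lp, x$S))
  cat(sprintf("best: %s (%d,%d) x (%d,%d), shift %d\n",
              x$best$orientation, x$best$k, x$best$l, x$best$m, x$best$n,
              x$best$shift))
  invisible(x)
}

#' Average register shift of a set of pairings
#'
#' Arithmetic mean of the canonical (non-negative) register shifts, typically
#' over the five best pairings of a sequence. Averages over however many
#' pairings are supplied.
#'
#' @param pairings a data frame with a `shift` column (e.g. the
#'   `top_pairings` element of a [best_pairings()] summary), a list of
#'   [beta_pairing()] objects, or a numeric vector of shifts.
#' @return The mean shift, a non-negative number.
#' @export
average_register_shift <- function(pairings) {
  if (is.numeric(pairings)) {
    shifts <- pairings
  } else if (is.data.frame(pairings)) {
    shifts <- pairings$shift
  } else if (is.list(pairings)) {
    shifts <- vapply(pairings, function(p) {
      stopifnot(inherits(p, "beta_pairing"))
      p$shift
    }, numeric(1))
  } else stop("unsupported pairings argument")
  if (!length(shifts)) stop("empty pairing list")
  mean(abs(shifts))
}

#' Scan a batch of sequences for their best-pairing features
#'
#' Runs [best_pairings()] over a set of sequences and tabulates the
#' per-sequence features used downstream: chain length `N`, best pairing
#' energy `E`, best pairing length `lp`, average register shift `S`, and the
#' best pairing's 1-based inclusive coordinates and orientation.
#'
#' @param records a data frame with columns `id` and `residues` (as returned
#'   by [read_fasta()]), or a named character vector of sequences.
#' @inheritParams best_pairings
#' @return A data frame with columns `id`, `N`, `E`, `lp`, `S`, `best_k`,
#'   `best_l`, `best_m`, `best_n`, `best_orientation`.
#' @export
scan_sequences <- function(records, tables, k_best = 5L, min_lp = 4L) {
  if (is.character(records)) {
    ids <- names(records) %||% as.character(seq_along(records))
    seqs <- unname(records)
  } else {
    stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
    ids <- records$id
    seqs <- records$residues
  }
  rows <- lapply(seq_along(seqs), function(i) {
    ps <- best_pairings(seqs[[i]], tables, k_best = k_best, min_lp = min_lp,
                        id = ids[[i]])
    data.frame(id = ids[[i]], N = ps$N, E = ps$E, lp = ps$lp, S = ps$S,
               best_k = ps$best$k, best_l = ps$best$l,
               best_m = ps$best$m, best_n = ps$best$n,
               best_orientation = ps$best$orientation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
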