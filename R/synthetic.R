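# synthetic-data generators: energy tables, labelled sequence sets, and
# feature tables from a planted linear score

#' Kyte-Doolittle hydropathy scale
#'
#' Residue hydropathy values from Kyte & Doolittle (1982), J Mol Biol 157,
#' 105-132. Used by the "hydrophobic" placeholder energy tables; any published
#' scale on which V, I, L, F rank highest would serve the same role.
#'
#' @format Named numeric vector over the 20 standard one-letter codes.
#' @export
kd_hydropathy <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                   V = 4.2, W = -0.9, Y = -1.3)

#' Generate placeholder residue-pair energy tables
#'
#' Synthetic stand-ins for published beta-pairing statistical potentials, for
#' testing and simulation (they are labelled synthetic and are not the
#' published parameter values). Styles:
#' \describe{
#'   \item{`zero`}{both tables identically 0.}
#'   \item{`hydrophobic`}{`e(a, b) = eps - h(a) h(b)` with `h` the
#'     Kyte-Doolittle hydropathy clipped at 0 and scaled to `[0, 1]` and
#'     `eps = 0.2` a small solvation penalty, so pairings of hydrophobic
#'     residues (V, I, L, F highest) are stabilising while polar background
#'     pairings cost energy; the antiparallel table is the parallel one scaled
#'     by 0.8, making the best pairing parallel.}
#'   \item{`random`}{i.i.d. normal entries (sd 0.5), seeded.}
#' }
#'
#' @param seed RNG seed (used by style `random`).
#' @param style one of `"zero"`, `"hydrophobic"`, `"random"`.
#' @return `list(parallel =, antiparallel =)` of [energy_table()] objects.
#' @export
generate_energy_tables <- function(seed = NULL, style = c("hydrophobic", "zero", "random")) {
  style <- match.arg(style)
  dn <- list(AA20, AA20)
  make <- function(m, o) energy_table(`dimnames<-`(m, dn), o)
  if (style == "zero") {
    z <- matrix(0, 20L, 20L)
    return(list(parallel = make(z, "parallel"),
                antiparallel = make(z, "antiparallel")))
  }
  if (style == "hydrophobic") {
    h <- pmax(kd_hydropathy[AA20], 0) / max(kd_hydropathy)
    par <- 0.2 - outer(h, h)
    return(list(parallel = make(par, "parallel"),
                antiparallel = make(0.8 * par, "antiparallel")))
  }
  with_seed(seed, {
    list(parallel = make(matrix(rnorm(400, sd = 0.5), 20L, 20L), "parallel"),
         antiparallel = make(matrix(rnorm(400, sd = 0.5), 20L, 20L), "antiparallel"))
  })
}

# polar-enriched background composition (normalised internally): hydrophobic
# beta-prone residues are rare, as in disordered linker regions
BACKGROUND_FREQ <- c(A = 0.040, C = 0.005, D = 0.070, E = 0.090, F = 0.010,
                     G = 0.090, H = 0.020, I = 0.010, K = 0.080, L = 0.020,
                     M = 0.005, N = 0.060, P = 0.070, Q = 0.080, R = 0.070,
                     S = 0.130, T = 0.090, V = 0.010, W = 0.005, Y = 0.020)

#' Generate a labelled synthetic sequence set with planted beta-prone stretches
#'
#' Emulates the phenomenology of phase-separating sequences detected through
#' beta-pairing features: positives are polar background sequences carrying
#' one short hydrophobic stretch (drawn from V/I/L/F, length 4-8 by default)
#' at a recorded position; negatives are pure background. Optionally appends
#' invalid records (too short, or containing non-standard letters) to
#' exercise the compatibility filter.
#'
#' @param n_pos,n_neg numbers of positive and negative sequences.
#' @param length_range inclusive range of valid sequence lengths; the default
#'   minimum of 140 keeps valid records above the compatibility filter's
#'   length threshold.
#' @param stretch_len integer vector of allowed planted-stretch lengths.
#' @param stretch_alphabet residues the planted stretch is drawn from.
#' @param background named residue frequency vector (normalised internally).
#' @param n_short,n_nonstandard numbers of additional invalid records:
#'   too-short sequences (length 30-139) and sequences containing an `X`.
#' @param seed RNG seed.
#' @return A list with `records` (data frame: `id`, `description`,
#'   `residues`) and `truth` (data frame: `id`, `label` (1 = positive),
#'   `planted_k`, `planted_l`; invalid records carry label `NA`).
#' @export
generate_sequences <- function(n_pos, n_neg, length_range = c(140L, 280L),
                               stretch_len = 4:8,
                               stretch_alphabet = c("V", "I", "L", "F"),
                               background = BACKGROUND_FREQ,
                               n_short = 0L, n_nonstandard = 0L, seed = NULL) {
  stopifnot(n_pos >= 0, n_neg >= 0, length_range[1L] <= length_range[2L],
            all(stretch_len >= 1), all(stretch_alphabet %in% AA20))
  if (length_range[1L] < max(stretch_len) + 2L && n_pos > 0)
    stop("planted stretch longer than the shortest sequence allows")
  bg <- background[AA20]
  if (anyNA(bg)) stop("background must name all 20 residues")
  bg <- bg / sum(bg)
  with_seed(seed, {
    draw_bg <- function(len) paste(sample(AA20, len, replace = TRUE, prob = bg),
                                   collapse = "")
    ids <- character(0); res <- character(0)
    label <- integer(0); pk <- integer(0); pl <- integer(0)
    for (i in seq_len(n_pos)) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      sl <- if (length(stretch_len) > 1L) sample(stretch_len, 1L) else stretch_len
      k <- sample(2L:(len - sl), 1L)
      s <- strsplit(draw_bg(len), "")[[1]]
      s[k:(k + sl - 1L)] <- sample(stretch_alphabet, sl, replace = TRUE)
      ids <- c(ids, sprintf("pos_%03d", i)); res <- c(res, paste(s, collapse = ""))
      label <- c(label, 1L); pk <- c(pk, k); pl <- c(pl, k + sl - 1L)
    }
    for (i in seq_len(n_neg)) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      ids <- c(ids, sprintf("neg_%03d", i)); res <- c(res, draw_bg(len))
      label <- c(label, 0L); pk <- c(pk, NA_integer_); pl <- c(pl, NA_integer_)
    }
    for (i in seq_len(n_short)) {
      ids <- c(ids, sprintf("short_%03d", i)); res <- c(res, draw_bg(sample(30:139, 1L)))
      label <- c(label, NA_integer_); pk <- c(pk, NA_integer_); pl <- c(pl, NA_integer_)
    }
    for (i in seq_len(n_nonstandard)) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      s <- strsplit(draw_bg(len), "")[[1]]
      s[sample(len, 1L)] <- "X"
      ids <- c(ids, sprintf("odd_%03d", i)); res <- c(res, paste(s, collapse = ""))
      label <- c(label, NA_integer_); pk <- c(pk, NA_integer_); pl <- c(pl, NA_integer_)
    }
    list(records = data.frame(id = ids,
                              description = rep("synthetic", length(ids)),
                              residues = res, stringsAsFactors = FALSE),
         truth = data.frame(id = ids, label = label, planted_k = pk,
                            planted_l = pl, stringsAsFactors = FALSE))
  })
}

#' Crude pi-contact frequency stub (NOT PScore)
#'
#' A deliberately crude per-sequence number proportional to the frequency of
#' residues with pi-bonding-capable sidechain or backbone context. It exists
#' only so synthetic pipelines have an external-score column to combine with
#' the pairing features; it shares none of the published PScore's eight terms
#' and must not be interpreted as a PScore.
#'
#' @param residues character vector of residue strings.
#' @return Numeric vector, one value per sequence.
#' @export
pi_contact_stub <- function(residues) {
  pi_res <- c("F", "W", "Y", "Q", "N", "E", "D", "R", "G", "P")
  vapply(residues, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    100 * mean(ch %in% pi_res)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a feature table from a planted linear score
#'
#' Draws feature vectors from fixed marginal distributions, computes the
#' planted composite score `s* = alpha* E/N + beta* ln(S+1) + gamma* ln(lp) + P`,
#' and assigns labels by a logistic rule
#' `P(positive) = plogis((s* - median(s*)) / temperature)`. Used for
#' weight-recovery and null-calibration tests of the training machinery.
#'
#' Feature marginals: `E/N ~ Normal(-0.055, 0.015)` (best pairing energies are
#' negative and scale with chain length), `S ~ Exponential(mean 2)`,
#' `lp ~ 4 + Poisson(6)`, `P ~ Normal(0, 2)`.
#'
#' @param n number of items.
#' @param weights named planted weights `alpha`, `beta`, `gamma`.
#' @param temperature logistic label-noise temperature; `0` gives noiseless,
#'   perfectly separable labels. The default, half the standard deviation of
#'   the planted scores, yields a realistic planted-scorer AUC in the
#'   mid-0.8s.
#' @param seed RNG seed.
#' @return A list with `features` (data frame: `id`, `E_over_N`, `S`, `lp`,
#'   `lnS1`, `lnlp`, `P`), `labels` (0/1), `planted_weights`, and
#'   `planted_scores` (the noiseless `s*`).
#' @export
generate_feature_dataset <- function(n = 2000L,
                                     weights = c(alpha = 86, beta = -0.56, gamma = -1.4),
                                     temperature = NULL, seed = NULL) {
  if (n < 4L) stop("need n >= 4")
  if (!all(c("alpha", "beta", "gamma") %in% names(weights)) ||
      any(!is.finite(weights)))
    stop("weights must be finite and name alpha, beta, gamma")
  with_seed(seed, {
    EN <- rnorm(n, -0.055, 0.015)
    S <- rexp(n, rate = 0.5)
    lp <- 4L + rpois(n, 6)
    P <- rnorm(n, 0, 2)
    fv <- data.frame(id = sprintf("sim_%05d", seq_len(n)),
                     E_over_N = EN, S = S, lp = lp,
                     lnS1 = log(S + 1), lnlp = log(lp), P = P,
                     stringsAsFactors = FALSE)
    s_star <- composite_score("s4", fv, weights[c("alpha", "beta", "gamma")])
    temp <- temperature %||% (sd(s_star) / 2)
    labels <- if (temp <= 0) as.integer(s_star > median(s_star))
              else rbinom(n, 1L, plogis((s_star - median(s_star)) / temp))
    list(features = fv, labels = labels,
         planted_weights = weights, planted_scores = s_star)
  })
}
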