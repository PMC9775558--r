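---
title: "Beta-pairing propensity as a phase-separation feature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-pairing propensity as a phase-separation feature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betapair)
```

## The model

`betapair` treats protein liquid–liquid phase separation (LLPS) prediction as
binary classification of sequences by a linear composite score. Two unrelated
interaction modes contribute: the ability to form planar π–π contacts,
summarised by an externally computed PScore `P`, and the propensity to
stabilise inter-chain cross-β pairing, summarised by three features extracted
from a PASTA-style scan of the sequence against itself.

A β-pairing hydrogen-bonds two equal-length stretches `(k, l)` and `(m, n)`
(1-based inclusive) of the same sequence, in parallel or antiparallel
orientation. Its energy is the sum of residue-pair energies from an
orientation-specific 20×20 statistical potential: row = residue of the
first (lower-start) stretch, column = partner residue; the partner stretch is
traversed forwards (parallel) or in reverse (antiparallel). The model assumes
a single pairing per chain, all other residues disordered, so the energy of
the best pairing is normalised by chain length (`E/N`, a Flory–Huggins-style
energy density) when it enters a score. Pairings are unordered, so they are
canonicalised to `m ≥ k`, which makes the register shift `S = m − k = n − l`
non-negative; `S = 0` is in-register self-pairing, the canonical amyloid
arrangement, and is allowed in both orientations.

The per-sequence features are `E` (lowest pairing energy), `lp` (length of
that best pairing) and `S̄` (mean register shift of the five best pairings).
The logarithmic transforms `ln(S+1)` and `ln(lp)` used in the composite
scores are the natural scale for counts of consecutive residues whose
constraint entropies grow logarithmically; `ln(S+1)` is finite at `S = 0`
precisely because shifts are canonicalised to be non-negative. The six
composite scores (`s0`, `s00`, `s1`–`s4`; see `?composite_score`) keep a unit
coefficient on `E/N` (for `s0`/`s00`) or on `P` (for `s1`–`s4`), which fixes
the scale of the remaining free weights and makes fitted weights comparable
across folds and runs.

The fractional position `f = min((m+n)/2N, 1 − (m+n)/2N)` of the best
pairing's first stretch measures how central the stretch sits in the chain
(`f = 1/2` at the centre, `f → 0` at a terminus). It is computed from the
1-based inclusive endpoints; under this convention the mirror image of a
stretch has an `f` differing by at most `1/N`, which is the documented
asymmetry of the definition. `compare_positional_sets()` compares two sets of
`f` values with the standard two-sample statistic
`Z = (mean_A − mean_B)/sqrt(sem_A² + sem_B²)`. Note that for two sets with
means 0.232 ± 0.020 and 0.158 ± 0.020 (mean ± s.e.m.) this formula gives
`Z ≈ 2.6`; larger published Z-values for comparable inputs must rest on a
different (unstated) statistic, and we deliberately implement only the
standard one.

## The scan and its tie-breaks

Enumerating all pairings is quartic in the chain length; the production scan
is quadratic. Parallel pairings with a common shift `s` live on the diagonal
`d_s(i) = e(seq[i], seq[i+s])`, where the optimal pairing is the minimum-sum
contiguous segment of length ≥ `min_lp` (prefix sums, linear per diagonal).
For antiparallel pairings the conserved quantity along a pairing is not the
shift but the *sum* `c = k + n` of paired positions, so the antiparallel
landscape decomposes into anti-diagonals `a_c(i) = e(seq[i], seq[c−i])` with
the canonicality constraint `k + l ≤ c`; the constrained minimum-sum segment
is still found in linear time by splitting the segment-end range into the
regime where the length bound binds and the regime where the canonicality
bound binds. Together the diagonals partition the full pairing set, so the
best diagonal optimum is exactly the global brute-force minimum — an
invariant the test suite checks on hundreds of random sequences and tables.

"Five best pairings" requires a de-duplication rule: the raw five lowest
energies are almost always one-residue trims of the same pairing, which would
make the average shift degenerate. We take one optimal pairing per diagonal
(per parallel shift, per antiparallel position-sum) and then the `k_best = 5`
lowest among these diagonal optima, so the top-5 differ in register, which is
what makes the average shift informative. This choice is ours; published
descriptions of PASTA-style top-k lists do not specify the rule.

Ties in energy are broken deterministically: longer pairing first, then
smaller shift, then smaller `k`, then parallel before antiparallel. This
favours the maximal in-register parallel pairing, the physically expected
best arrangement, and makes every result reproducible bit-for-bit.

Tunable parameters of the scan:

* `min_lp` (default 4, residues) — minimum pairing length. One- or
  two-residue "pairings" are not β-structure; 4 matches the short (4–8
  residue) hydrophobic stretches typically picked out in phase-separating
  sequences.
* `k_best` (default 5) — number of diagonal optima over which the average
  register shift is taken; if a short sequence has fewer candidates the
  average is over what exists.
* Energy tables are used exactly as loaded, never symmetrised implicitly;
  `symmetrize_energy_table()` is available when a parameter set is defined
  only up to symmetrisation.

## Evaluation machinery

`auc()` integrates the empirical step ROC by trapezoids, which equals the
rank statistic `P(score_pos > score_neg) + ½ P(tie)`; the test suite checks
this equivalence against an independent pairwise-comparison oracle and
against `pROC`. Predictions use the `score ≥ threshold` convention; since ROC
construction steps through distinct score values, the tie convention never
changes the AUC. `mcc()` returns 0 whenever a denominator factor vanishes,
which reproduces the ROC-corner identities (`TP = FP = 0` and `TN = FN = 0`
both give MCC 0). `max_mcc()` sweeps thresholds midway between consecutive
distinct scores plus the two infinite corners and breaks ties towards the
highest threshold. `mcc_dilution_check()` exposes the size-dilution property
of the MCC — at fixed sensitivity and false-alarm rate, MCC → 0 as the
negative set grows — which is why MCC values are only comparable between
negative sets of similar size while AUC is not affected.

`compare_auc_distributions()` is a one-way fixed-effects ANOVA (via
`stats::lm`/`anova`) reporting F, p and `η² = SS_between/SS_total`; in the
degenerate all-between-variance case the `F = ∞, p = 0, η² = 1` limit is
returned. When fold-level AUCs from a common cross-validation are pooled as
groups, the values are not strictly independent; the ANOVA is reported as a
descriptive comparison under that caveat. `ks_normality()` tests against a
normal with estimated mean and sd using the plain Kolmogorov–Smirnov null
distribution. With estimated parameters this p-value is biased upwards
(the Lilliefors correction would shrink it), so it is used only in the
liberal direction: deciding whether a mean or a median summarises a fold
distribution.

## Training

Weights are fitted by maximising the exact rank AUC of the composite score on
the training set with Nelder–Mead (`stats::optim`). The empirical AUC is
piecewise constant in the weights, so a single simplex run can stall on a
plateau; the optimiser is multi-started from the zero vector (which reduces
`s1`–`s4` to `P` alone and guarantees the fitted training AUC is at least the
`P`-only AUC) plus `restarts = 5` random starts whose scale is set by the
ratio of the fixed term's spread to each feature's spread. The best restart
is kept; the reported AUC is always the exact rank AUC, never a smoothed
surrogate.

`cross_validate()` repeats `M = 25` random unstratified partitions of the
pooled positive+negative set into `k = 5` folds (both configurable; an
optional stratified mode exists but is off by default, matching the plain
"random partition of the union" protocol). Each fold serves once as test
set; weights are fitted on the other `k − 1` folds; test AUC and test
max-MCC are recorded, giving `k × M` fold results. Defaults follow the
common protocol of 5 folds and 25 realisations; where a 4-fold variant of
the same protocol is wanted, `k` is a configuration knob. Folds that end up
single-class (possible with tiny synthetic sets) are skipped with a warning
rather than aborting the run. The summary reports each weight and measure as
mean ± sd when the fold distribution is compatible with normality by
`ks_normality()` (p > 0.05) and median ± sd otherwise, and those summary
values are the consensus weights used by `coef()`, `predict()` and `plot()`.
All randomness (partitions and restarts) derives from one user seed, so a
fixed seed reproduces a run bit-for-bit.

## What the synthetic generators emulate — and what they do not

The package trains and evaluates with no external downloads via three
generators, all seeded and bitwise-reproducible:

* `generate_energy_tables()` — placeholder potentials, *not* the published
  PASTA2 parameters. The `"hydrophobic"` style sets
  `e(a, b) = 0.2 − h(a)·h(b)` with `h` the Kyte–Doolittle hydropathy clipped
  at zero and scaled to `[0, 1]` (V, I, L, F highest) and scales the
  antiparallel table by 0.8. The positive offset acts as a solvation
  penalty: a pure product of a non-negative vector would make every pairing
  stabilising and the best pairing trivially the whole chain. Real
  statistical potentials favour β-pairing of hydrophobic residues; this
  style reproduces that ranking (`e(V,V) < e(S,S)`) without claiming the
  published values.
* `generate_sequences()` — positives are polar-background chains (length
  140–280 by default, above the compatibility filter's threshold) carrying
  one planted V/I/L/F stretch of length 4–8 at a recorded position,
  negatives pure background; optional too-short or non-standard-letter
  records exercise the filter. This emulates the observed phenomenology —
  short hydrophobic β-prone stretches flanked by charged/polar residues —
  not real proteome composition, disorder content, or low-complexity
  domains.
* `generate_feature_dataset()` — feature vectors from fixed marginals with
  labels drawn from a logistic rule on a planted `s4`; the default planted
  weights `(α, β, γ) = (86, −0.56, −1.4)` are of the magnitude that trained
  composite scores reach on real data, and the default temperature (half the
  planted-score sd) puts the planted scorer's AUC in the mid-0.8s, a
  realistic operating point chosen once from that design consideration.

Consequently, passing tests demonstrate that the machinery is correct — the
scan finds the true optimum, training recovers planted weights to within
their fold-to-fold spread, composites beat a signal-free baseline when the
pairing features carry all the signal — but say nothing about predictive
performance on real phase-separation datasets, which depends on the actual
PASTA2 tables, the real PScore and curated positive/negative sets.

## Numerical and interface conventions

* All coordinates in tables and outputs are 1-based inclusive.
* Sequences shorter than 140 residues or containing letters outside the
  20-letter alphabet are dropped by `filter_sequences()` (the threshold is
  configurable), mirroring the compatibility rules of the external PScore
  script; sequences without a PScore are excluded from composite scoring,
  never imputed.
* Energies are dimensionless; lower is more stabilising; composite scores
  are oriented so that higher predicts phase separation.
* Degenerate inputs error early with messages naming the offending residue,
  row/column, or id (missing table rows, non-numeric cells, duplicate FASTA
  ids, empty records, single-class inputs to AUC).

Problem sizes in the shipped tests were chosen so the whole suite runs in
well under a minute of CPU: oracle equivalence on 200 random sequences of
length ≤ 30, planted-weight recovery at n = 2000 with 10 folds, end-to-end
benchmarks with 100 sequences of length 140–280. The quadratic scan handles
chains of a few thousand residues in well under a second, so real proteome
scans are practical.

## Known limitations

* Intra-chain pairing and hetero-sequence (two-protein) co-aggregation are
  out of scope: the scan pairs a sequence only with a copy of itself.
* No length-dependent correction or per-pairing free-energy offset is
  applied to pairing energies; if a parameter set expects one, it must be
  folded into the table.
* The consensus weights are a cross-fold location estimate, not a refit on
  all data; for final production weights one may refit on the full dataset
  with `optimize_weights()`.
* AUC-maximisation targets ranking quality; if the deployment loss is
  threshold-specific (e.g. MCC at fixed false-alarm rate), the trained
  weights are not guaranteed optimal for it.
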