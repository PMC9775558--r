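test_that("score_pairing implements the orientation-specific summations", {
  zt <- zero_tables()
  p <- beta_pairing(1, 2, 3, 4, "parallel")
  expect_equal(score_pairing("AVLI", p, zt$parallel), 0)

  par <- matrix(0, 20, 20); par[match("V", AA), match("V", AA)] <- -1
  expect_equal(score_pairing("VVVV", p, make_table(par, "parallel")), -2)

  # antiparallel: (1,2) x (3,4) on "AVLI" pairs A with I and V with L;
  # hand-evaluated term-by-term on an asymmetric toy table
  anti <- matrix(0, 20, 20); dimnames(anti) <- list(AA, AA)
  anti["A", "I"] <- -0.7; anti["I", "A"] <- 9 # asymmetric on purpose
  anti["V", "L"] <- 0.3;  anti["L", "V"] <- -9
  pa <- beta_pairing(1, 2, 3, 4, "antiparallel")
  expect_equal(score_pairing("AVLI", pa, energy_table(anti, "antiparallel")),
               -0.7 + 0.3)

  expect_error(score_pairing("AVLI", beta_pairing(1, 3, 3, 5, "parallel"),
                             zt$parallel), "index error")
  expect_error(score_pairing("AXLI", p, zt$parallel), "alphabet error")
})

test_that("pairings are unordered: (A,B) scores as canonicalised (B,A)", {
  set.seed(41)
  for (orient in c("parallel", "antiparallel")) {
    tab <- make_table(matrix(rnorm(400), 20, 20), orient)
    s <- random_seq(12)
    ab <- beta_pairing(2, 5, 7, 10, orient)
    ba <- beta_pairing(7, 10, 2, 5, orient)
    expect_equal(score_pairing(s, ba, tab), score_pairing(s, ab, tab))
    expect_equal(ba$shift, 5L)
  }
})

test_that("enumerate_pairings generates the exact canonical candidate set", {
  zt <- zero_tables()
  expect_equal(nrow(enumerate_pairings(strrep("A", 5), zt["parallel"], min_lp = 2)), 20L)
  expect_equal(nrow(enumerate_pairings(strrep("A", 5), zt, min_lp = 2)), 40L)
  both <- enumerate_pairings(strrep("A", 4), zt, min_lp = 4)
  expect_equal(nrow(both), 2L)
  expect_true(all(both$shift == 0L))
  expect_error(enumerate_pairings("", zt, min_lp = 2), "empty sequence")
})

test_that("homopolymer V8 with e(V,V) = -1 gives E = -8, lp = 8, S = 2", {
  par <- matrix(0, 20, 20); par[match("V", AA), match("V", AA)] <- -1
  tabs <- list(parallel = make_table(par, "parallel"),
               antiparallel = zero_tables()$antiparallel)
  ps <- best_pairings(strrep("V", 8), tabs, k_best = 5, min_lp = 4)
  expect_equal(ps$E, -8)
  expect_equal(ps$lp, 8L)
  expect_equal(ps$best$shift, 0L)
  expect_equal(sort(ps$top_pairings$shift), 0:4)
  expect_equal(ps$S, 2)
  # brute-force oracle agrees on the global best
  bf <- enumerate_pairings(strrep("V", 8), tabs, min_lp = 4)
  expect_equal(bf$energy[1L], -8)
})

test_that("all-zero tables give E = 0 and the documented tie-broken best", {
  ps <- best_pairings(random_seq(10), zero_tables(), min_lp = 3)
  expect_equal(ps$E, 0)
  # longest, in-register, leftmost, parallel-first
  expect_equal(ps$best[c("k", "l", "m", "n", "shift")],
               list(k = 1L, l = 10L, m = 1L, n = 10L, shift = 0L))
  expect_identical(ps$best$orientation, "parallel")
})

test_that("k_best = 1 makes S the best pairing's own shift", {
  set.seed(7)
  tabs <- generate_energy_tables(seed = 7, style = "random")
  s <- random_seq(20)
  ps1 <- best_pairings(s, tabs, k_best = 1, min_lp = 4)
  expect_equal(ps1$S, ps1$best$shift)
})

test_that("average_register_shift is the mean canonical shift", {
  expect_equal(average_register_shift(c(0, 1, 2, 3, 4)), 2)
  expect_equal(average_register_shift(data.frame(shift = c(0, 0, 0))), 0)
  expect_equal(average_register_shift(list(beta_pairing(1, 4, 4, 7, "parallel"))), 3)
  expect_error(average_register_shift(numeric(0)), "empty")
})

test_that("diagonal-scan best pairing equals the brute-force minimum", {
  set.seed(123)
  for (i in 1:50) {
    N <- sample(6:28, 1)
    min_lp <- sample(2:5, 1)
    s <- random_seq(N)
    tabs <- generate_energy_tables(seed = i, style = "random")
    bf <- enumerate_pairings(s, tabs, min_lp = min_lp)
    bp <- best_pairings(s, tabs, min_lp = min_lp)
    expect_equal(bp$E, bf$energy[1L], tolerance = 1e-12)
    expect_equal(unlist(bp$best[c("k", "l", "m", "n", "shift")]),
                 unlist(bf[1L, c("k", "l", "m", "n", "shift")]))
    expect_identical(bp$best$orientation, bf$orientation[1L])
  }
})

test_that("per-shift parallel optimum is the min-sum segment of its diagonal", {
  set.seed(99)
  for (i in 1:10) {
    N <- sample(10:24, 1)
    min_lp <- 3
    s <- random_seq(N)
    tabs <- generate_energy_tables(seed = 100 + i, style = "random")
    bf <- enumerate_pairings(s, tabs["parallel"], min_lp = min_lp)
    code <- match(strsplit(s, "")[[1]], AA)
    mat <- unclass(tabs$parallel)
    for (shift in c(0L, 2L, N - min_lp)) {
      if (shift > N - min_lp) next
      diag_vals <- vapply(seq_len(N - shift), function(j) {
        mat[code[j], code[j + shift]]
      }, numeric(1))
      expect_equal(min(bf$energy[bf$shift == shift]),
                   min_sum_segment_oracle(diag_vals, min_lp))
    }
  }
})

test_that("prepending non-participating residues translates coordinates", {
  # give R uniformly positive energies so it can never improve a pairing
  set.seed(55)
  m <- matrix(abs(rnorm(400)) + 0.1, 20, 20)
  hyd <- match(c("V", "I", "L", "F"), AA)
  m[hyd, hyd] <- -abs(rnorm(16)) - 0.5
  tabs <- list(parallel = make_table(m, "parallel"),
               antiparallel = make_table(m * 0.9, "antiparallel"))
  s <- "GGVILFVILGG"
  base <- best_pairings(s, tabs, min_lp = 3)
  shifted <- best_pairings(paste0("RRRR", s), tabs, min_lp = 3)
  expect_equal(shifted$E, base$E)
  expect_equal(shifted$best$k, base$best$k + 4L)
  expect_equal(shifted$best$m, base$best$m + 4L)
})

test_that("a constant table shift lowers the best energy by c times its length", {
  set.seed(77)
  s <- random_seq(15)
  tabs <- generate_energy_tables(seed = 77, style = "random")
  cshift <- 0.4
  shifted <- list(
    parallel = make_table(unclass(tabs$parallel)[AA, AA] - cshift, "parallel"),
    antiparallel = make_table(unclass(tabs$antiparallel)[AA, AA] - cshift,
                              "antiparallel"))
  bf <- enumerate_pairings(s, tabs, min_lp = 3)
  bf2 <- enumerate_pairings(s, shifted, min_lp = 3)
  # brute-force oracle: new minimum is min over pairings of (E - c * lp)
  expect_equal(bf2$energy[1L], min(bf$energy - cshift * bf$lp))
  expect_equal(best_pairings(s, shifted, min_lp = 3)$E, bf2$energy[1L])
})

test_that("scan_sequences tabulates per-sequence features with 1-based coords", {
  tabs <- generate_energy_tables(style = "hydrophobic")
  seqs <- c(a = "SSSSVVVVVVSSSS", b = "QQQQILFVQQQQQQ")
  tab <- scan_sequences(seqs, tabs, min_lp = 4)
  expect_equal(tab$id, c("a", "b"))
  expect_equal(tab$N, c(14L, 14L))
  expect_true(all(tab$E < 0))
  expect_equal(tab$best_k[1L], 5L)
  expect_equal(tab$best_l[1L], 10L)
  expect_identical(tab$best_orientation, c("parallel", "parallel"))
})
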