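test_that("hand-derived sentence polarities are reproduced", {
  sc <- function(toks) score_sentence(toks, FIX$binary, FIX$shifter, PCONF)
  # bare +1 anchor in a 2-word sentence: 1/sqrt(2)
  expect_equal(sc(c("paciente", "estable"))$delta, 1 / sqrt(2))
  # negated +1 anchor: sign reversed
  expect_equal(sc(c("no", "contento"))$delta, -1 / sqrt(2))
  # amplified +1 anchor: (1 + 0.8)/sqrt(2)
  expect_equal(sc(c("muy", "contento"))$delta, 1.8 / sqrt(2))
  # deamplified: (1 - 0.8)/sqrt(2)
  expect_equal(sc(c("poco", "contento"))$delta, 0.2 / sqrt(2))
  # no lexicon match
  expect_identical(sc(c("sin", "novedad"))$delta, 0)
  # comma truncation cuts the negator out of the cluster
  expect_equal(sc(c("no", ",", "contento"))$delta, 1 / sqrt(2))
  # comma does not count as a word in n
  expect_equal(sc(c("a", ",", "contento"))$delta, 1 / sqrt(2))
  # deamplifier floor: three deamplifiers give max(-1, -2.4) -> weight 0
  expect_equal(score_sentence(c("poco", "apenas", "algo", "contento"),
                              FIX$binary, FIX$shifter,
                              polarity_config(before = 4))$delta, 0)
})

test_that("cluster traces satisfy their structural invariants", {
  sp <- score_sentence(c("x1", "no", "muy", "contento", "poco", ","),
                       FIX$binary, FIX$shifter, PCONF)
  expect_length(sp$traces, 1L)
  tr <- sp$traces[[1]]
  expect_false(tr$anchor_index %in% tr$cluster_indices)
  expect_identical(tr$n_negators + tr$n_amplifiers + tr$n_deamplifiers +
                     tr$n_neutral, length(tr$cluster_indices))
  expect_identical(tr$n_negators, 1L)
  expect_identical(tr$n_amplifiers, 1L)
  expect_identical(tr$n_deamplifiers, 1L)
  expect_equal(sp$delta, sum(vapply(sp$traces, `[[`, 0, "weighted_value")) /
                 sqrt(sp$n_words))
})

test_that("scorer equals the brute-force oracle on the full fixture grid", {
  fx <- build_polarity_fixtures()
  got <- vapply(fx$tokens, function(toks)
    score_sentence(toks, FIX$binary, FIX$shifter, PCONF)$delta, 0)
  expect_identical(got, fx$delta)
})

test_that("polarity properties hold on randomized sentences", {
  flipped <- FIX$binary
  flipped$entries <- -flipped$entries
  set.seed(404)
  for (rep in 1:200) {
    toks <- random_sentence(sample(3:12, 1))
    sp <- score_sentence(toks, FIX$binary, FIX$shifter, PCONF)
    # sign equivariance under lexicon flip
    expect_equal(score_sentence(toks, flipped, FIX$shifter, PCONF)$delta,
                 -sp$delta)
    # sqrt(n) padding law: appending k out-of-cluster neutral words
    k <- 3L
    padded <- c(toks, rep("pp", k))
    expect_equal(score_sentence(padded, FIX$binary, FIX$shifter, PCONF)$delta,
                 sp$delta * sqrt(sp$n_words / (sp$n_words + k)))
  }
})

test_that("negator parity flips and amplifier monotonicity hold", {
  base <- c("f1", "f2", "contento")
  d0 <- score_sentence(base, FIX$binary, FIX$shifter, PCONF)$delta
  n1 <- c("f1", "no", "contento")
  n2 <- c("nunca", "no", "contento")
  d1 <- score_sentence(n1, FIX$binary, FIX$shifter, PCONF)$delta
  d2 <- score_sentence(n2, FIX$binary, FIX$shifter, PCONF)$delta
  expect_equal(d1, -d0)
  expect_equal(d2, d0)
  a1 <- score_sentence(c("f1", "muy", "contento"), FIX$binary, FIX$shifter,
                       PCONF)$delta
  expect_gt(a1, d0)
  dd <- score_sentence(c("f1", "poco", "contento"), FIX$binary, FIX$shifter,
                       PCONF)$delta
  expect_lt(dd, d0)
  expect_gte(dd, 0)  # floored at (1 + deamp_floor) = 0
})

test_that("note_polarity is the unweighted sentence mean", {
  expect_identical(note_polarity(0.4), 0.4)
  expect_identical(note_polarity(c(0.3, -0.3)), 0)
  expect_equal(note_polarity(c(0.1, 0.2, 0.6)), 0.3)
  expect_error(note_polarity(numeric(0)))
})

test_that("fourier_trend keeps low frequencies and shrinks noise", {
  expect_equal(fourier_trend(rep(2, 16)), rep(2, 16))
  t <- 0:31
  wave <- cos(2 * pi * t / 32)
  expect_equal(fourier_trend(wave, k_low = 1), wave, tolerance = 1e-9)
  set.seed(5)
  noise <- rnorm(64)
  sm <- fourier_trend(noise, k_low = 3)
  expect_lt(var(sm), var(noise))
  expect_warning(out <- fourier_trend(1:6, k_low = 3), "nothing to filter")
  expect_identical(out, 1:6)
})

test_that("mann_whitney matches hand enumeration and wilcox.test", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw$U, 0)
  ref <- wilcox.test(c(1, 2, 3), c(4, 5, 6), correct = TRUE, exact = FALSE)
  expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
  # ties: cross-check against wilcox.test normal approximation
  x <- c(1, 2, 2, 3, 5, 5, 7); y <- c(2, 3, 3, 5, 6, 8)
  mw2 <- mann_whitney(x, y)
  ref2 <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(unname(mw2$U), unname(ref2$statistic))
  expect_equal(mw2$p, ref2$p.value, tolerance = 1e-10)
  id <- mann_whitney(1:20, 1:20)
  expect_equal(id$Z, 0, tolerance = 0.1)
  expect_gt(id$p, 0.9)
})

test_that("lilliefors test behaves sensibly and flags constant samples", {
  set.seed(8)
  x <- rnorm(100)
  res <- lilliefors_test(x, n_mc = 500, seed = 2)
  expect_gt(res$p, 0.01)
  y <- rexp(100)     # clearly non-normal
  expect_lt(lilliefors_test(y, n_mc = 500, seed = 2)$p, 0.05)
  expect_error(lilliefors_test(rep(1, 10)), "constant")
})

test_that("compare_groups returns the full report", {
  set.seed(9)
  res <- compare_groups(list(covid = rnorm(40, 0.1), non_covid = rnorm(40)),
                        n_mc = 300, seed = 3)
  expect_named(res$ks_lilliefors, c("covid", "non_covid"))
  expect_true(is.finite(res$mann_whitney$Z))
  expect_error(compare_groups(list(a = rnorm(4), b = rnorm(40))), ">= 8")
  same <- compare_groups(list(a = rep(c(1, 2), 10), b = rep(c(1, 2), 10)),
                         n_mc = 200, seed = 4)
  expect_equal(same$mann_whitney$Z, 0, tolerance = 1e-12)
  expect_equal(same$mann_whitney$p, 1)
})
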