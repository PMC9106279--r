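disjoint_corpus <- function(n_per = 30L, len = 25L, seed = 71L) {
  # two doc sets over disjoint vocabularies
  set.seed(seed)
  va <- sprintf("a%02d", 1:20); vb <- sprintf("b%02d", 1:20)
  docs <- c(lapply(seq_len(n_per), function(i) sample(va, len, replace = TRUE)),
            lapply(seq_len(n_per), function(i) sample(vb, len, replace = TRUE)))
  list(docs = docs, va = va, vb = vb)
}

test_that("fit_lda separates disjoint vocabularies and conserves structure", {
  dc <- disjoint_corpus()
  m <- fit_lda(dc$docs, K = 2, alpha = 0.5, eta = 0.01, n_iter = 200,
               burn_in = 100, thin = 5, seed = 5)
  expect_rows_sum_to_one(m$beta_hat)
  expect_rows_sum_to_one(m$theta_hat)
  truth <- rbind(a = rep(c(1 / 20, 0), c(20, 20)),
                 b = rep(c(0, 1 / 20), c(20, 20)))
  colnames(truth) <- m$vocab
  mt <- match_topics(m$beta_hat, truth)
  expect_true(all(mt$tv < 0.1))
  # determinism
  m2 <- fit_lda(dc$docs, K = 2, alpha = 0.5, eta = 0.01, n_iter = 200,
                burn_in = 100, thin = 5, seed = 5)
  expect_identical(m$beta_hat, m2$beta_hat)
  expect_error(fit_lda(list(character(0)), K = 2), ">= 1 token")
})

test_that("K = 1 recovers smoothed empirical word frequencies in closed form", {
  docs <- list(c("a", "a", "b"), c("b", "c", "c", "c"))
  m <- fit_lda(docs, K = 1, alpha = 1, eta = 0.5, n_iter = 20, burn_in = 10,
               thin = 2, seed = 1)
  counts <- c(a = 2, b = 2, c = 3)
  expect_equal(as.numeric(m$beta_hat),
               as.numeric((counts + 0.5) / (7 + 3 * 0.5)), tolerance = 1e-12)
  expect_equal(as.numeric(m$theta_hat), c(1, 1))
})

test_that("Gibbs log-likelihood improves from initialization to convergence", {
  dc <- disjoint_corpus(seed = 73L)
  m <- fit_lda(dc$docs, K = 2, alpha = 0.5, eta = 0.01, n_iter = 100,
               burn_in = 50, thin = 5, seed = 6)
  ll <- m$loglik
  expect_gt(mean(tail(ll, 20)), mean(head(ll, 5)))
})

test_that("semantic coherence follows its formula and separates K choices", {
  # closed-form check on a tiny fitted model with known doc frequencies
  docs <- list(c("a", "b"), c("a", "b"), c("a", "c"))
  m <- fit_lda(docs, K = 1, alpha = 1, eta = 0.1, n_iter = 20, burn_in = 10,
               thin = 2, seed = 2)
  # beta ranks: a (3) > b (2) > c (1); D(a)=3, D(b)=2, D(c)=1,
  # D(a,b)=2, D(a,c)=1, D(b,c)=0
  expected <- log((2 + 1) / 2) + log((1 + 1) / 1) + log((0 + 1) / 1)
  expect_equal(semantic_coherence(m, M = 3), expected, tolerance = 1e-12)
  expect_error(semantic_coherence(m, M = 10), "vocabulary")
  # saturated co-occurrence: every pair contributes log((D+1)/D) > log 1
  docs2 <- rep(list(c("a", "b", "c")), 5)
  m2 <- fit_lda(docs2, K = 1, alpha = 1, eta = 0.1, n_iter = 20, burn_in = 10,
                thin = 2, seed = 3)
  expect_equal(semantic_coherence(m2, M = 3), 3 * log(6 / 5), tolerance = 1e-12)
})

test_that("exclusivity is ~1 for disjoint topics and drops for duplicated ones", {
  dc <- disjoint_corpus(seed = 77L)
  m <- fit_lda(dc$docs, K = 2, alpha = 0.5, eta = 0.01, n_iter = 200,
               burn_in = 100, thin = 5, seed = 7)
  expect_true(all(exclusivity(m) > 0.95))
  # duplicated identical topics: every word's share is 1/2, so the score
  # hits the closed-form harmonic bound with the frequency quantile at 1
  dup <- m
  dup$beta_hat <- rbind(m$beta_hat[1, ], m$beta_hat[1, ])
  exc <- exclusivity(dup, M = 5)
  # independent closed form at equal betas: share = 1/2 for every word,
  # frequency quantile straight from the ECDF of the duplicated row
  row <- m$beta_hat[1, ]
  q <- ecdf(row)(sort(row, decreasing = TRUE)[1:5])
  expect_equal(exc[1], mean(1 / (0.7 / 0.5 + 0.3 / q)), tolerance = 1e-12)
  expect_lt(exc[1], 1 / (0.7 / 0.5 + 0.3))  # below the 0.5-share bound
  expect_equal(exc[1], exc[2])
})

test_that("select_K returns the grid frontier and a sane selection", {
  one <- generate_lda_corpus(K = 3, V = 60, D = 80, doc_len = 30, alpha = 0.2,
                             eta = 0.01, seed = 19)
  single <- select_K(one$docs, K_grid = 4L, eta = 0.01, n_iter = 100,
                     burn_in = 50, thin = 5, seed = 8, vocab = one$vocab)
  expect_identical(single$selected_K, 4L)
  expect_identical(nrow(single$frontier), 1L)
  expect_error(select_K(one$docs, K_grid = c(1, 5)), "K_grid")
})

test_that("planted-K corpus has higher coherence at K* than at K*+5", {
  lc <- generate_lda_corpus(K = 4, V = 120, D = 150, doc_len = 40,
                            alpha = 0.1, eta = 0.01, seed = 21)
  fit_at <- function(K) fit_lda(lc$docs, K, alpha = 0.1, eta = 0.01,
                                n_iter = 200, burn_in = 100, thin = 5,
                                seed = 9, vocab = lc$vocab)
  m_true <- fit_at(4L); m_over <- fit_at(9L)
  expect_gt(mean(semantic_coherence(m_true)), mean(semantic_coherence(m_over)))
  expect_gt(mean(exclusivity(m_true)), mean(exclusivity(m_over)))
})

test_that("match_topics undoes a known permutation", {
  set.seed(31)
  beta <- t(vapply(1:4, function(i) { x <- rgamma(30, 0.1); x / sum(x) },
                   numeric(30)))
  perm <- c(3, 1, 4, 2)
  mt <- match_topics(beta[perm, ], beta)
  expect_identical(order(perm), mt$perm)   # inverse permutation recovered
  expect_true(all(mt$tv < 1e-12))
})

test_that("prevalence_effects finds a planted group-tilted topic", {
  tilt <- matrix(1, 3, 4); tilt[, 2] <- 5
  cc <- generate_corpus(synth_config(
    seed = 37L, n_patients = 8L, n_topics_true = 4L,
    date_range = c("2020-01-01", "2020-03-30"), duplicate_rate = 0,
    prevalence_shift = list(covid = tilt), polarity_truth = FALSE))
  covs <- data.frame(group = cc$notes$group,
                     month = notepol:::month_index(cc$notes$date))
  pe <- prevalence_effects(cc$truth$true_doc_topic, covs, n_perm = 199,
                           seed = 10)
  expect_lt(pe$effects$p_group[2], 0.05)
  expect_gt(pe$effects$group_effect[2], 0)   # covid minus non_covid
  expect_true(all(pe$effects$p_group >= 0 & pe$effects$p_group <= 1))
  expect_identical(dim(pe$correlation), c(4L, 4L))
  expect_equal(unname(diag(pe$correlation)), rep(1, 4))
  expect_identical(pe$correlation, t(pe$correlation))
})

test_that("correlated topic proportions produce a network edge", {
  set.seed(41)
  n <- 300
  base <- matrix(rgamma(n * 4, 0.5), n, 4)
  base[, 2] <- base[, 1] * 0.9 + base[, 2] * 0.1   # topics 1-2 co-vary
  theta <- base / rowSums(base)
  covs <- data.frame(group = rep(c("covid", "non_covid"), length.out = n),
                     month = rep(1:3, length.out = n))
  pe <- prevalence_effects(theta, covs, n_perm = 99, seed = 11)
  expect_true(any(pe$edges$topic_a == 1 & pe$edges$topic_b == 2))
})

test_that("single-group corpora skip group terms", {
  set.seed(43)
  theta <- matrix(rgamma(200 * 3, 1), 200, 3)
  theta <- theta / rowSums(theta)
  covs <- data.frame(group = "covid", month = rep(1:4, each = 50))
  pe <- prevalence_effects(theta, covs, n_perm = 99, seed = 12)
  expect_true(pe$single_group)
  expect_true(all(is.na(pe$effects$p_group)))
  expect_true(all(is.finite(pe$effects$month_p)))
})

test_that("topic_concentration reads theta mass of the top documents", {
  theta <- rbind(c(1, 0), c(1, 0), c(0.5, 0.5), c(0, 1))  # 4 docs, 2 topics
  conc <- topic_concentration(theta, frac = 0.25)         # top 1 document
  expect_equal(unname(conc), c(1 / 2.5, 1 / 1.5))
  uni <- matrix(1 / 3, 30, 3)
  expect_equal(unname(topic_concentration(uni, frac = 0.1)), rep(0.1, 3))
})

test_that("top_words returns the requested shape", {
  dc <- disjoint_corpus(seed = 79L)
  m <- fit_lda(dc$docs, K = 2, alpha = 0.5, eta = 0.01, n_iter = 100,
               burn_in = 50, thin = 5, seed = 13)
  tw <- top_words(m, M = 5)
  expect_identical(nrow(tw), 10L)
  expect_identical(unique(tw$rank), 1:5)
})
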