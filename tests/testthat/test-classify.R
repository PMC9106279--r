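test_that("split_dtm is stratified, deterministic, and ~75/25", {
  dtm <- planted_dtm()
  s1 <- split_dtm(dtm, seed = 3)
  s2 <- split_dtm(dtm, seed = 3)
  expect_identical(s1$split, s2$split)
  expect_identical(sum(s1$split == "train"), 90L)
  for (cl in c("covid", "non_covid")) {
    in_train <- sum(s1$split == "train" & s1$labels == cl)
    expect_lte(abs(in_train - 0.75 * 60), 1)
  }
  bad <- dtm; bad$labels <- rep("covid", length(bad$labels))
  expect_error(split_dtm(bad, seed = 1), "both classes")
})

test_that("naive Bayes learns class-specific words and degenerates to priors", {
  x <- rbind(c(3, 0), c(2, 0), c(0, 2), c(0, 3), c(0, 1))
  colnames(x) <- c("wa", "wb")
  y <- c("A", "A", "B", "B", "B")
  m <- fit_naive_bayes(x, y)
  test_x <- matrix(c(2, 0), 1, dimnames = list(NULL, c("wa", "wb")))
  pred <- predict(m, test_x)
  expect_identical(pred$labels, "A")   # wa occurs only in class A
  # uniform counts: likelihood cancels, posterior = priors
  xu <- matrix(1, 4, 2, dimnames = list(NULL, c("wa", "wb")))
  yu <- c("A", "B", "B", "B")
  mu <- fit_naive_bayes(xu, yu)
  pu <- predict(mu, matrix(1, 1, 2))
  expect_equal(pu$scores, log(3 / 4) - log(1 / 4), tolerance = 1e-12)
})

test_that("evaluate reproduces hand-computed confusion metrics", {
  cm <- confusion_metrics(matrix(c(40, 10, 5, 45), 2, byrow = TRUE))
  expect_equal(cm$accuracy, 0.85)
  expect_equal(cm$kappa, 0.70, tolerance = 1e-12)
  # perfect classifier
  truth <- rep(c("covid", "non_covid"), each = 10)
  scores <- rep(c(1, -1), each = 10)
  labels <- truth
  r <- evaluate(scores, labels, truth, positive = "covid")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$kappa, 1)
  expect_lt(r$accuracy_p, 0.001)
  expect_error(evaluate(scores, labels, rep("covid", 20)), "single-class")
})

test_that("accuracy CI and significance agree with binom.test", {
  truth <- rep(c("covid", "non_covid"), c(12, 8))
  labels <- c(rep("covid", 10), rep("non_covid", 10))
  scores <- as.numeric(labels == "covid")
  r <- evaluate(scores, labels, truth, positive = "covid")
  k <- sum(labels == truth)
  ref <- binom.test(k, 20, p = 12 / 20, alternative = "greater")
  expect_equal(r$accuracy_p, ref$p.value, tolerance = 1e-12)
  ref_ci <- binom.test(k, 20)$conf.int
  expect_equal(r$accuracy_ci95, as.numeric(ref_ci), tolerance = 1e-12)
})

test_that("rank AUC equals the exhaustive pairwise oracle, ties included", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(8:50, 1)
    truth <- sample(c("covid", "non_covid"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("covid", "non_covid")
    scores <- sample(seq(-1, 1, by = 0.25), n, replace = TRUE)  # forced ties
    labels <- ifelse(scores > 0, "covid", "non_covid")
    r <- evaluate(scores, labels, truth, positive = "covid")
    expect_identical(r$auc, auc_pairwise(scores, truth, "covid"))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(59)
  truth <- sample(c("covid", "non_covid"), 40, replace = TRUE)
  truth[1:2] <- c("covid", "non_covid")
  scores <- rnorm(40)
  labels <- ifelse(scores > 0, "covid", "non_covid")
  a0 <- evaluate(scores, labels, truth, positive = "covid")$auc
  for (f in list(function(x) 3 * x + 2, function(x) exp(x), function(x) x^3)) {
    expect_equal(evaluate(f(scores), labels, truth, positive = "covid")$auc, a0)
  }
})

test_that("constant predictions give kappa 0 on balanced truth, random AUC ~ 0.5", {
  truth <- rep(c("covid", "non_covid"), 20)
  labels <- rep("covid", 40)
  scores <- rep(0, 40)
  r <- evaluate(scores, labels, truth, positive = "covid")
  expect_equal(r$kappa, 0)
  expect_equal(r$auc, 0.5)
  set.seed(61)
  aucs <- replicate(200, {
    evaluate(rnorm(40), labels, truth, positive = "covid")$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("the model suite shares one split and isolates backend failures", {
  dtm <- planted_dtm()
  boom <- list(name = "boom", fit = function(x, y) stop("nope"),
               predict = function(m, x) NULL)
  suite <- run_model_suite(dtm, backends = list(naive_bayes = backend_nb(),
                                                boom = boom), seed = 7)
  expect_identical(nrow(suite$table), 2L)
  expect_gt(suite$table$accuracy[1], 0.95)
  expect_gt(suite$table$auc[1], 0.95)
  expect_identical(suite$table$error[2], "nope")
  # same seed -> identical split across calls
  suite2 <- run_model_suite(dtm, seed = 7)
  expect_identical(suite$split, suite2$split)
})

test_that("the glmnet backend satisfies the pluggable contract", {
  dtm <- planted_dtm()
  suite <- run_model_suite(dtm, backends = list(nb = backend_nb(),
                                                ridge = backend_glmnet()),
                           seed = 9)
  expect_true(all(suite$table$auc > 0.9))
})
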