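#' Build a document-term matrix from tokenized notes
#'
#' Features are content-lemma counts (bags of words; no tf-idf by default,
#' the simplest reading of "comments" as documents — `tfidf = TRUE` applies
#' the standard log-idf weighting).
#'
#' @param toks list of `notepol_tokenized_note` objects.
#' @param labels group label per note.
#' @param tfidf weight counts by `log(D / df)`.
#' @return `notepol_dtm`: `x` (docs x vocab numeric matrix), `vocab`,
#'   `labels`, `note_ids`.
#' @export
build_dtm <- function(toks, labels, tfidf = FALSE) {
  stopifnot(length(toks) == length(labels))
  bags <- lapply(toks, function(tk) unlist(tk$content_lemmas, use.names = FALSE))
  vocab <- sort(unique(unlist(bags, use.names = FALSE)))
  x <- matrix(0, length(bags), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(bags)) {
    tb <- table(bags[[i]])
    x[i, names(tb)] <- as.numeric(tb)
  }
  if (tfidf) {
    df <- colSums(x > 0)
    x <- sweep(x, 2, log(nrow(x) / pmax(df, 1)), "*")
  }
  structure(list(x = x, vocab = vocab, labels = as.character(labels),
                 note_ids = vapply(toks, `[[`, "", "note_id")),
            class = "notepol_dtm")
}

#' Stratified train/test split
#'
#' Random 75/25 split stratified by class: within each class,
#' `round(train_frac * n_class)` documents go to training, so overall
#' proportions are within one document of the target.
#'
#' @param dtm a `notepol_dtm`.
#' @param train_frac training fraction.
#' @param seed integer.
#' @return the dtm with an added `split` factor (`train`/`test`).
#' @export
split_dtm <- function(dtm, train_frac = 0.75, seed = 1L) {
  stopifnot(inherits(dtm, "notepol_dtm"), nrow(dtm$x) >= 8L)
  if (length(unique(dtm$labels)) < 2L) stop("both classes must be present", call. = FALSE)
  assign <- rep("test", nrow(dtm$x))
  with_seed(seed, {
    for (cl in unique(dtm$labels)) {
      idx <- which(dtm$labels == cl)
      n_train <- round(train_frac * length(idx))
      assign[sample(idx, n_train)] <- "train"
    }
  })
  dtm$split <- assign
  dtm
}

#' Multinomial naive Bayes with Laplace smoothing
#'
#' @param x docs x vocab count matrix (training rows).
#' @param y class labels (two classes).
#' @return `notepol_nb`: per-class log priors and add-1-smoothed log word
#'   probabilities; `positive_class` is the alphabetically-last class, the
#'   one scored by [predict.notepol_nb()].
#' @export
fit_naive_bayes <- function(x, y) {
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2L, nrow(x) == length(y))
  log_prior <- log(table(factor(y, classes)) / length(y))
  log_prob <- t(vapply(classes, function(cl) {
    wc <- colSums(x[y == cl, , drop = FALSE])
    log((wc + 1) / sum(wc + 1))
  }, numeric(ncol(x))))
  structure(list(classes = classes, log_prior = as.numeric(log_prior),
                 log_prob = log_prob, positive_class = classes[2L]),
            class = "notepol_nb")
}

#' Predict with a fitted naive Bayes model
#'
#' @param object a `notepol_nb`.
#' @param newdata docs x vocab matrix with the training vocabulary.
#' @param ... unused.
#' @return list `scores` (posterior log-odds of the positive class) and
#'   `labels` (argmax posterior).
#' @export
predict.notepol_nb <- function(object, newdata, ...) {
  ll <- newdata %*% t(object$log_prob)
  post <- sweep(ll, 2, object$log_prior, "+")
  scores <- post[, 2L] - post[, 1L]
  labels <- object$classes[(scores > 0) + 1L]
  list(scores = as.numeric(scores), labels = labels)
}

# Rank-based (Mann-Whitney) AUC with mid-rank tie handling.
auc_rank <- function(scores, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate classifier scores and labels against truth
#'
#' AUC by the rank formulation with mid-rank ties; sensitivity/specificity
#' and Cohen's kappa from the confusion matrix at the supplied decision
#' labels; exact Clopper-Pearson 95% CI for accuracy; and a one-sided exact
#' binomial test of accuracy against the no-information rate (the majority
#' class share of the truth), the standard meaning of "accuracy P value"
#' in this workflow.
#'
#' @param scores numeric scores (larger = more positive-class).
#' @param labels predicted class labels.
#' @param truth true class labels (both classes present).
#' @param positive the positive class (default: alphabetically last).
#' @return `notepol_eval_report`: `auc`, `sensitivity`, `specificity`,
#'   `kappa`, `accuracy`, `accuracy_ci95`, `accuracy_p`, `nir`,
#'   `confusion`.
#' @export
evaluate <- function(scores, labels, truth,
                     positive = sort(unique(truth))[length(unique(truth))]) {
  n <- length(truth)
  stopifnot(n >= 4L, length(scores) == n, length(labels) == n)
  if (length(unique(truth)) < 2L) {
    stop("single-class truth: AUC and kappa undefined", call. = FALSE)
  }
  classes <- sort(unique(truth))
  negative <- setdiff(classes, positive)
  tp <- sum(labels == positive & truth == positive)
  fn <- sum(labels != positive & truth == positive)
  tn <- sum(labels != positive & truth != positive)
  fp <- sum(labels == positive & truth != positive)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(pred = c(positive, negative),
                                      truth = c(positive, negative)))
  acc_k <- tp + tn
  accuracy <- acc_k / n
  po <- accuracy
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  nir <- max(table(truth)) / n
  ci <- c(if (acc_k == 0) 0 else qbeta(0.025, acc_k, n - acc_k + 1),
          if (acc_k == n) 1 else qbeta(0.975, acc_k + 1, n - acc_k))
  accuracy_p <- pbinom(acc_k - 1L, n, nir, lower.tail = FALSE)
  structure(list(auc = auc_rank(scores, truth, positive),
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 kappa = kappa, accuracy = accuracy, accuracy_ci95 = ci,
                 accuracy_p = accuracy_p, nir = nir, confusion = confusion,
                 positive_class = positive),
            class = "notepol_eval_report")
}

#' Metrics straight from a confusion matrix
#'
#' Convenience for hand-checkable cases: rows = predicted, columns = truth,
#' positive class first.
#'
#' @param confusion 2 x 2 numeric matrix.
#' @return list `accuracy`, `kappa`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(confusion) {
  tp <- confusion[1, 1]; fp <- confusion[1, 2]
  fn <- confusion[2, 1]; tn <- confusion[2, 2]
  n <- sum(confusion)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(accuracy = po, kappa = (po - pe) / (1 - pe),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Built-in classifier backends
#'
#' A backend is a list with `fit(x, y) -> model` and
#' `predict(model, x) -> list(scores, labels)`. `backend_nb()` is the
#' native multinomial naive Bayes; `backend_glmnet()` (ridge-penalized
#' logistic regression, requires the suggested glmnet package) demonstrates
#' how external learners — SVMs, random forests, neural networks — plug
#' into the same contract.
#'
#' @return a backend list.
#' @export
backend_nb <- function() {
  list(name = "naive_bayes",
       fit = function(x, y) fit_naive_bayes(x, y),
       predict = function(model, x) predict(model, x))
}

#' @rdname backend_nb
#' @param lambda ridge penalty.
#' @export
backend_glmnet <- function(lambda = 0.1) {
  list(name = "ridge_logistic",
       fit = function(x, y) {
         if (!requireNamespace("glmnet", quietly = TRUE)) {
           stop("backend_glmnet requires the 'glmnet' package", call. = FALSE)
         }
         classes <- sort(unique(y))
         fit <- glmnet::glmnet(x, factor(y, classes), family = "binomial",
                               alpha = 0, lambda = lambda)
         list(fit = fit, classes = classes)
       },
       predict = function(model, x) {
         s <- as.numeric(glmnet::predict.glmnet(model$fit, x))
         list(scores = s, labels = model$classes[(s > 0) + 1L])
       })
}

#' Run a suite of classifier backends on one shared split
#'
#' All backends see the identical stratified split and are scored with the
#' identical metric suite; a failing backend is isolated (its row carries
#' the error message) rather than aborting the suite.
#'
#' @param dtm a `notepol_dtm` (split applied here if absent).
#' @param backends named list of backends (default: native naive Bayes).
#' @param train_frac,seed forwarded to [split_dtm()] when needed.
#' @return list `reports` (per backend: `notepol_eval_report` or error),
#'   `table` (data.table in model x metric shape), `split`.
#' @export
run_model_suite <- function(dtm, backends = list(naive_bayes = backend_nb()),
                            train_frac = 0.75, seed = 1L) {
  if (is.null(dtm$split)) dtm <- split_dtm(dtm, train_frac, seed)
  tr <- dtm$split == "train"
  reports <- list()
  for (nm in names(backends)) {
    be <- backends[[nm]]
    reports[[nm]] <- tryCatch({
      model <- be$fit(dtm$x[tr, , drop = FALSE], dtm$labels[tr])
      pred <- be$predict(model, dtm$x[!tr, , drop = FALSE])
      evaluate(pred$scores, pred$labels, dtm$labels[!tr])
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "notepol_backend_error"))
  }
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (inherits(r, "notepol_backend_error")) {
      data.table::data.table(model = nm, auc = NA_real_, sensitivity = NA_real_,
                             specificity = NA_real_, kappa = NA_real_,
                             accuracy = NA_real_, accuracy_lo = NA_real_,
                             accuracy_hi = NA_real_, accuracy_p = NA_real_,
                             error = r$message)
    } else {
      data.table::data.table(model = nm, auc = r$auc,
                             sensitivity = r$sensitivity,
                             specificity = r$specificity, kappa = r$kappa,
                             accuracy = r$accuracy,
                             accuracy_lo = r$accuracy_ci95[1],
                             accuracy_hi = r$accuracy_ci95[2],
                             accuracy_p = r$accuracy_p, error = NA_character_)
    }
  })
  list(reports = reports, table = data.table::rbindlist(rows),
       split = dtm$split)
}
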