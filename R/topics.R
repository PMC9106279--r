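#' Fit LDA by collapsed Gibbs sampling
#'
#' Symmetric-prior latent Dirichlet allocation estimated with a collapsed
#' Gibbs sampler (C++ inner loop, driven by R's RNG so a fixed seed gives a
#' fixed fit). `beta_hat` and `theta_hat` are posterior means over the
#' post-burn-in thinned sweeps.
#'
#' @param docs list of documents: character token vectors, or 1-based
#'   integer word ids when `vocab` is supplied.
#' @param K topic count (>= 2... K = 1 is allowed as the degenerate
#'   closed-form case and bypasses sampling variance concerns).
#' @param alpha document-topic Dirichlet concentration (default `50 / K`).
#' @param eta topic-word Dirichlet concentration.
#' @param n_iter,burn_in,thin Gibbs schedule.
#' @param seed integer.
#' @param vocab optional character vocabulary; inferred from tokens
#'   otherwise.
#' @return `notepol_lda`: `K`, `vocab`, `beta_hat` (K x V), `theta_hat`
#'   (D x K), `loglik` trace, `hyperparams`, `seed`.
#' @export
fit_lda <- function(docs, K, alpha = 50 / K, eta = 0.01,
                    n_iter = 1000L, burn_in = 500L, thin = 10L,
                    seed = 1L, vocab = NULL) {
  stopifnot(K >= 1L, length(docs) >= 1L)
  if (is.null(vocab)) {
    if (!is.character(docs[[1]])) stop("supply `vocab` for integer docs", call. = FALSE)
    vocab <- sort(unique(unlist(docs, use.names = FALSE)))
    docs <- lapply(docs, function(d) match(d, vocab))
  } else {
    docs <- lapply(docs, function(d)
      if (is.character(d)) match(d, vocab) else as.integer(d))
  }
  if (any(vapply(docs, length, 0L) == 0L)) stop("every document needs >= 1 token", call. = FALSE)
  if (any(vapply(docs, anyNA, TRUE))) stop("token outside vocabulary", call. = FALSE)
  V <- length(vocab)
  if (V < K) stop("vocabulary smaller than K", call. = FALSE)
  if (V == 0L) stop("empty vocabulary", call. = FALSE)
  res <- with_seed(seed,
    lda_gibbs_cpp(docs, as.integer(K), alpha, eta, V,
                  as.integer(n_iter), as.integer(burn_in), as.integer(thin)))
  beta_hat <- res$beta_hat
  theta_hat <- res$theta_hat
  colnames(beta_hat) <- vocab
  rownames(beta_hat) <- paste0("topic", seq_len(K))
  colnames(theta_hat) <- paste0("topic", seq_len(K))
  structure(list(K = as.integer(K), vocab = vocab, beta_hat = beta_hat,
                 theta_hat = theta_hat, loglik = res$loglik,
                 hyperparams = list(alpha = alpha, eta = eta,
                                    n_iter = n_iter, burn_in = burn_in,
                                    thin = thin),
                 seed = seed, docs = docs),
            class = "notepol_lda")
}

#' Top words of each topic
#'
#' @param model a `notepol_lda`.
#' @param M words per topic.
#' @return data.table (topic, rank, word, beta).
#' @export
top_words <- function(model, M = 10L) {
  rows <- lapply(seq_len(model$K), function(k) {
    o <- order(model$beta_hat[k, ], decreasing = TRUE)[seq_len(min(M, length(model$vocab)))]
    data.table::data.table(topic = k, rank = seq_along(o),
                           word = model$vocab[o],
                           beta = model$beta_hat[k, o])
  })
  data.table::rbindlist(rows)
}

#' Per-topic semantic coherence
#'
#' For each topic's top-`M` words ranked by `beta_hat`, sums
#' `log((D(w_i, w_j) + 1) / D(w_j))` over ranked pairs `i < j`, where
#' `D(.)` counts documents containing the word(s). Always <= 0 for words
#' that occur; closer to 0 is better (top words co-occur in documents).
#' Pairs whose conditioning word never occurs contribute 0.
#'
#' @param model a `notepol_lda`.
#' @param docs documents used to count co-occurrence (defaults to the
#'   fitting corpus).
#' @param M top words per topic.
#' @return numeric vector, one value per topic.
#' @export
semantic_coherence <- function(model, docs = model$docs, M = 10L) {
  if (M > length(model$vocab)) stop("M exceeds vocabulary size", call. = FALSE)
  vapply(seq_len(model$K), function(k) {
    top <- order(model$beta_hat[k, ], decreasing = TRUE)[seq_len(M)]
    # binary presence of each top word per document
    pres <- vapply(top, function(w)
      vapply(docs, function(d) any(d == w), TRUE), logical(length(docs)))
    Dw <- colSums(pres)
    co <- crossprod(pres)
    s <- 0
    for (i in seq_len(M - 1L)) {
      for (j in seq((i + 1L), M)) {
        if (Dw[j] > 0) s <- s + log((co[i, j] + 1) / Dw[j])
      }
    }
    s
  }, 0)
}

#' Per-topic FREX exclusivity
#'
#' For each of a topic's top-`M` words, the score is the weighted harmonic
#' mean of (a) the word's exclusivity share
#' `beta[t, w] / sum_t' beta[t', w]` and (b) the word's within-topic
#' frequency quantile (ECDF of `beta[t, ]`):
#' `1 / (w_f / share + (1 - w_f) / freq_q)` with exclusivity weight
#' `frex_weight`. Values are in (0, 1]; higher means the topic's top words
#' are not shared with other topics.
#'
#' @param model a `notepol_lda`.
#' @param M top words per topic.
#' @param frex_weight weight on the exclusivity component.
#' @return numeric vector, one value per topic.
#' @export
exclusivity <- function(model, M = 10L, frex_weight = 0.7) {
  beta <- model$beta_hat
  share <- sweep(beta, 2, colSums(beta), "/")
  vapply(seq_len(model$K), function(k) {
    top <- order(beta[k, ], decreasing = TRUE)[seq_len(min(M, ncol(beta)))]
    freq_q <- ecdf(beta[k, ])(beta[k, top])
    mean(1 / (frex_weight / share[k, top] + (1 - frex_weight) / freq_q))
  }, 0)
}

#' Select the topic count by coherence and exclusivity
#'
#' Fits one model per candidate `K` on a fixed seed schedule, computes the
#' mean semantic coherence and mean exclusivity of each, and selects the
#' `K` maximizing the sum of the two criteria's ranks (both "higher is
#' better"; ties break toward the smaller K). The full frontier is
#' returned so a human can override the automatic choice.
#'
#' @param docs corpus (as in [fit_lda()]).
#' @param K_grid integer candidates within \[2, 50\].
#' @param alpha,eta,n_iter,burn_in,thin,seed,vocab forwarded to [fit_lda()];
#'   each K derives its own seed from `seed`.
#' @param M top words used by both criteria.
#' @return `notepol_topic_diagnostics`: `frontier` (data.table K,
#'   coherence, exclusivity, rank_sum), `selected_K`, `models` (list).
#' @export
select_K <- function(docs, K_grid, alpha = NULL, eta = 0.01,
                     n_iter = 1000L, burn_in = 500L, thin = 10L,
                     seed = 1L, M = 10L, vocab = NULL) {
  stopifnot(all(K_grid >= 2L), all(K_grid <= 50L), length(K_grid) >= 1L)
  models <- list(); coh <- numeric(0); exc <- numeric(0)
  for (K in K_grid) {
    m <- fit_lda(docs, K, alpha = if (is.null(alpha)) 50 / K else alpha,
                 eta = eta, n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = derive_seed(seed, paste0("selectK_", K)), vocab = vocab)
    models[[as.character(K)]] <- m
    coh <- c(coh, mean(semantic_coherence(m, M = M)))
    exc <- c(exc, mean(exclusivity(m, M = M)))
  }
  rank_sum <- rank(coh, ties.method = "average") +
    rank(exc, ties.method = "average")
  frontier <- data.table::data.table(K = as.integer(K_grid), coherence = coh,
                                     exclusivity = exc, rank_sum = rank_sum)
  selected_K <- frontier$K[order(-frontier$rank_sum, frontier$K)][1L]
  structure(list(frontier = frontier, selected_K = selected_K,
                 models = models),
            class = "notepol_topic_diagnostics")
}

#' Topic concentration (specificity)
#'
#' How concentrated each topic is in few documents: the share of a topic's
#' total \eqn{\hat\theta} mass carried by its top `frac` fraction of
#' documents. Values near 1 mean the topic is assigned to a handful of
#' notes (high specificity); `K/D`-uniform theta gives roughly `frac`.
#' Descriptive only — no test is attached.
#'
#' @param model a `notepol_lda` (or theta matrix).
#' @param frac fraction of top documents (default 0.1).
#' @return numeric vector, one value per topic.
#' @export
topic_concentration <- function(model, frac = 0.1) {
  theta <- if (inherits(model, "notepol_lda")) model$theta_hat else as.matrix(model)
  n_top <- max(1L, floor(frac * nrow(theta)))
  apply(theta, 2, function(col)
    sum(sort(col, decreasing = TRUE)[seq_len(n_top)]) / sum(col))
}

#' Match estimated topics to reference topics
#'
#' Greedy assignment minimizing total-variation distance between rows of
#' two row-stochastic matrices over a shared vocabulary; used to undo label
#' switching before any comparison to planted truth.
#'
#' @param beta_est,beta_ref row-stochastic matrices with identical columns.
#' @return list `perm` (for each reference row, the matched estimated row)
#'   and `tv` (matched total-variation distances).
#' @export
match_topics <- function(beta_est, beta_ref) {
  stopifnot(ncol(beta_est) == ncol(beta_ref))
  Kr <- nrow(beta_ref); Ke <- nrow(beta_est)
  tvmat <- matrix(0, Kr, Ke)
  for (i in seq_len(Kr)) for (j in seq_len(Ke)) {
    tvmat[i, j] <- 0.5 * sum(abs(beta_ref[i, ] - beta_est[j, ]))
  }
  perm <- integer(Kr); tv <- numeric(Kr)
  open_r <- seq_len(Kr); open_e <- seq_len(Ke)
  work <- tvmat
  for (step in seq_len(min(Kr, Ke))) {
    best <- which(work == min(work), arr.ind = TRUE)[1, ]
    ri <- open_r[best[1]]; ej <- open_e[best[2]]
    perm[ri] <- ej; tv[ri] <- tvmat[ri, ej]
    open_r <- open_r[-best[1]]; open_e <- open_e[-best[2]]
    work <- work[-best[1], -best[2], drop = FALSE]
  }
  if (length(open_r)) {    # more reference rows than estimated rows
    for (ri in open_r) {
      perm[ri] <- which.min(tvmat[ri, ])
      tv[ri] <- min(tvmat[ri, ])
    }
  }
  list(perm = perm, tv = tv)
}

#' Post hoc covariate prevalence effects on document-topic proportions
#'
#' The paper-style structural model places covariates inside the topic
#' prior; here, as a declared approximation, plain-LDA `theta_hat` columns
#' are regressed on group, month index and their interaction, with
#' significance for the group and interaction terms from permutation of
#' group labels within month strata. Topic correlations are Pearson
#' correlations of the `theta_hat` columns; network edges keep pairs with
#' `|r| >=` `cor_threshold`.
#'
#' @param model a `notepol_lda` (or a bare theta matrix).
#' @param covariates data.frame with columns `group` and `month`
#'   (month index, numeric), one row per document.
#' @param n_perm permutation replicates.
#' @param seed integer.
#' @param cor_threshold network edge threshold on `|r|`.
#' @return `notepol_prevalence_effects`: `effects` (data.table per topic:
#'   group_effect = difference in mean theta, group_coef, month_trend,
#'   month_p, interaction, p_group, p_interaction), `correlation` (K x K),
#'   `edges` (data.table), `n_perm`.
#' @export
prevalence_effects <- function(model, covariates, n_perm = 999L, seed = 1L,
                               cor_threshold = 0.3) {
  theta <- if (inherits(model, "notepol_lda")) model$theta_hat else as.matrix(model)
  stopifnot(nrow(theta) == nrow(covariates),
            all(c("group", "month") %in% names(covariates)))
  K <- ncol(theta)
  grp <- covariates$group
  mon <- as.numeric(covariates$month)
  # center the month index so the group main effect is the group contrast
  # at the average month rather than an extrapolation to month zero
  mon_c <- mon - mean(mon)
  single_group <- length(unique(grp)) < 2L
  lev <- sort(unique(grp))
  g01 <- as.numeric(grp == lev[1L])
  # indicator on the first sorted level ("covid" before "non_covid"), so
  # group_effect / group_coef read as first level minus second

  fit_coefs <- function(gvec) {
    X <- cbind(1, gvec, mon_c, gvec * mon_c)
    cf <- stats::lm.fit(X, theta)$coefficients
    list(group = cf[2, ], inter = cf[4, ])
  }

  if (single_group) {
    X <- cbind(1, mon)
    fit <- stats::lm.fit(X, theta)
    month_trend <- fit$coefficients[2, ]
    res <- theta - X %*% fit$coefficients
    df <- nrow(theta) - 2L
    se <- sqrt(colSums(res^2) / df / sum((mon - mean(mon))^2))
    month_p <- 2 * stats::pt(-abs(month_trend / se), df)
    effects <- data.table::data.table(
      topic = seq_len(K), group_effect = NA_real_, group_coef = NA_real_,
      month_trend = month_trend, month_p = month_p,
      interaction = NA_real_, p_group = NA_real_, p_interaction = NA_real_)
  } else {
    obs <- fit_coefs(g01)
    # analytic month-trend t-test from the full model
    X <- cbind(1, g01, mon_c, g01 * mon_c)
    qrX <- qr(X)
    cf <- qr.coef(qrX, theta)
    res <- theta - X %*% cf
    df <- nrow(theta) - ncol(X)
    XtXinv <- chol2inv(qr.R(qrX))
    se_m <- sqrt(colSums(res^2) / df * XtXinv[3, 3])
    month_p <- 2 * stats::pt(-abs(cf[3, ] / se_m), df)

    perm_g <- matrix(0, n_perm, K)
    perm_i <- matrix(0, n_perm, K)
    strata <- split(seq_along(mon), mon)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        gp <- g01
        for (s in strata) gp[s] <- gp[sample(s)]
        pc <- fit_coefs(gp)
        perm_g[b, ] <- pc$group
        perm_i[b, ] <- pc$inter
      }
    })
    p_group <- vapply(seq_len(K), function(k)
      (1 + sum(abs(perm_g[, k]) >= abs(obs$group[k]))) / (n_perm + 1), 0)
    p_inter <- vapply(seq_len(K), function(k)
      (1 + sum(abs(perm_i[, k]) >= abs(obs$inter[k]))) / (n_perm + 1), 0)
    gdiff <- colMeans(theta[grp == lev[1L], , drop = FALSE]) -
      colMeans(theta[grp == lev[2L], , drop = FALSE])
    effects <- data.table::data.table(
      topic = seq_len(K), group_effect = gdiff, group_coef = obs$group,
      month_trend = cf[3, ], month_p = month_p, interaction = obs$inter,
      p_group = p_group, p_interaction = p_inter)
  }

  cmat <- stats::cor(theta)
  dimnames(cmat) <- list(paste0("topic", seq_len(K)), paste0("topic", seq_len(K)))
  pairs <- which(upper.tri(cmat) & abs(cmat) >= cor_threshold, arr.ind = TRUE)
  edges <- data.table::data.table(topic_a = pairs[, 1], topic_b = pairs[, 2],
                                  r = cmat[pairs])
  structure(list(effects = effects, correlation = cmat, edges = edges,
                 n_perm = as.integer(n_perm), single_group = single_group),
            class = "notepol_prevalence_effects")
}
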