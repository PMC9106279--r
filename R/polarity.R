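#' Polarity scoring configuration
#'
#' Controls the context-cluster geometry and shifter weighting of the
#' sentence polarity score. Defaults follow the standard augmented-
#' dictionary method: a cluster of 4 words before and 2 after each
#' polarized word, truncation at a comma preceding the anchor, shifter
#' weight `c = 0.8`, and a deamplifier floor of -1 (so the multiplicative
#' factor `1 + amp_total` never goes below 0).
#'
#' @param before,after cluster extent in token positions around the anchor.
#' @param c weight applied per amplifier/deamplifier.
#' @param deamp_floor lower bound on the summed amplifier weight.
#' @param comma_truncation drop cluster tokens at or before the last comma
#'   on the anchor's left.
#' @return `notepol_polarity_config`.
#' @export
polarity_config <- function(before = 4L, after = 2L, c = 0.8,
                            deamp_floor = -1, comma_truncation = TRUE) {
  stopifnot(before >= 0L, after >= 0L, c > 0, deamp_floor <= 0)
  structure(list(before = as.integer(before), after = as.integer(after),
                 c = c, deamp_floor = deamp_floor,
                 comma_truncation = isTRUE(comma_truncation)),
            class = "notepol_polarity_config")
}

# The single point where shifter counts combine into a cluster weight:
# parity sign flip for negators, additive +/- c per (de)amplifier with the
# deamplifier floor. Isolated so an alternative combination rule can be
# swapped in without touching the cluster scan.
cluster_weight <- function(p, n_neg, n_amp, n_deamp, config) {
  amp_total <- max(config$deamp_floor, config$c * (n_amp - n_deamp))
  p * (-1)^n_neg * (1 + amp_total)
}

#' Sentence polarity with valence-shifter context clusters
#'
#' For every token with a binary-lexicon polarity \eqn{p \in \{-1, +1\}}, a
#' context cluster of up to `before` tokens on the left and `after` on the
#' right is formed (a comma to the left truncates the cluster to the tokens
#' after it; comma tokens themselves are never cluster members). Cluster
#' tokens are classified by the shifter lexicon as negators, amplifiers or
#' deamplifiers (else neutral), the anchor's weight is
#' \eqn{p \cdot (-1)^{n_{neg}} (1 + \max(floor,\; c\,(n_{amp} - n_{deamp})))},
#' and the sentence polarity is
#' \eqn{\delta = \sum_i w_i / \sqrt{n}} with `n` the sentence word count,
#' commas excluded. Overlapping clusters from adjacent polarized words are
#' scored independently.
#'
#' @param tokens character vector: one lowercased sentence, commas as
#'   standalone `","` tokens (see [tokenize_and_split()]).
#' @param binary_lexicon,shifter_lexicon `notepol_lexicon` objects.
#' @param config a [polarity_config()].
#' @param note_id,sentence_index carried into the result for bookkeeping.
#' @return `notepol_sentence_polarity`: `delta`, `n_words`, and `traces`
#'   (per anchor: index, p, cluster indices, shifter counts, weight).
#' @export
score_sentence <- function(tokens, binary_lexicon, shifter_lexicon,
                           config = polarity_config(),
                           note_id = NA_character_, sentence_index = NA_integer_) {
  stopifnot(length(tokens) >= 1L, inherits(config, "notepol_polarity_config"))
  pol <- binary_lexicon$entries
  roles <- shifter_lexicon$entries
  is_comma <- tokens == ","
  n_words <- sum(!is_comma)
  traces <- list()
  total <- 0
  if (n_words > 0L) {
    anchors <- which(!is_comma & tokens %in% names(pol))
    for (i in anchors) {
      p <- unname(pol[[tokens[i]]])
      left <- seq_len(i - 1L)
      left <- left[left >= i - config$before]
      if (config$comma_truncation) {
        commas_left <- left[is_comma[left]]
        if (length(commas_left)) left <- left[left > max(commas_left)]
      }
      right <- i + seq_len(config$after)
      right <- right[right <= length(tokens)]
      cluster <- c(left, right)
      cluster <- cluster[!is_comma[cluster]]
      role <- unname(roles[tokens[cluster]])
      n_neg <- sum(role == "negator", na.rm = TRUE)
      n_amp <- sum(role == "amplifier", na.rm = TRUE)
      n_deamp <- sum(role == "deamplifier", na.rm = TRUE)
      w <- cluster_weight(p, n_neg, n_amp, n_deamp, config)
      total <- total + w
      traces[[length(traces) + 1L]] <- list(
        anchor_index = i, p = p, cluster_indices = cluster,
        n_negators = n_neg, n_amplifiers = n_amp, n_deamplifiers = n_deamp,
        n_neutral = length(cluster) - n_neg - n_amp - n_deamp,
        weighted_value = w)
    }
  }
  structure(list(note_id = note_id, sentence_index = sentence_index,
                 delta = if (n_words > 0L) total / sqrt(n_words) else 0,
                 n_words = n_words, traces = traces),
            class = "notepol_sentence_polarity")
}

#' Polarity of every sentence in a corpus
#'
#' Polarity deliberately runs on the raw lowercased sentences (stopwords
#' retained): negators and amplifiers are function words. Set
#' `use_lemmas = TRUE` to score lemmatized sentences instead.
#'
#' @param toks list of `notepol_tokenized_note` objects.
#' @param binary_lexicon,shifter_lexicon lexicons.
#' @param config a [polarity_config()].
#' @param use_lemmas score `lemmas` instead of surface `sentences`.
#' @return data.table (note_id, sentence_index, delta, n_words).
#' @export
polarity_corpus <- function(toks, binary_lexicon, shifter_lexicon,
                            config = polarity_config(), use_lemmas = FALSE) {
  rows <- list()
  for (tk in toks) {
    sents <- if (use_lemmas) tk$lemmas else tk$sentences
    for (si in seq_along(sents)) {
      sp <- score_sentence(sents[[si]], binary_lexicon, shifter_lexicon,
                           config, note_id = tk$note_id, sentence_index = si)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        note_id = tk$note_id, sentence_index = si,
        delta = sp$delta, n_words = sp$n_words)
    }
  }
  data.table::rbindlist(rows)
}

#' Note-level polarity
#'
#' Unweighted mean of the note's sentence polarities — group comparisons in
#' this workflow are at the note (comment) level.
#'
#' @param sentence_deltas numeric vector of the note's sentence scores.
#' @return scalar mean.
#' @export
note_polarity <- function(sentence_deltas) {
  stopifnot(length(sentence_deltas) >= 1L)
  mean(sentence_deltas)
}

#' Low-pass Fourier smoothing of a polarity series
#'
#' Confirms a polarity trend by discrete Fourier transform: the DC
#' component plus the `k_low` lowest nonzero frequencies (with conjugate
#' partners) are retained and the series inverse-transformed.
#'
#' @param series numeric vector (ordered note or sentence polarities).
#' @param k_low number of nonzero frequencies kept.
#' @return real numeric vector of the same length. If
#'   `k_low >= floor(length/2)` the input is returned unchanged with a
#'   warning.
#' @export
fourier_trend <- function(series, k_low = 3L) {
  stopifnot(length(series) >= 4L, k_low >= 1L, all(is.finite(series)))
  N <- length(series)
  if (k_low >= floor(N / 2)) {
    warning("k_low >= floor(length/2): nothing to filter, returning input",
            call. = FALSE)
    return(series)
  }
  X <- fft(series)
  keep <- c(1L, 1L + seq_len(k_low), N + 1L - seq_len(k_low))
  X[setdiff(seq_len(N), keep)] <- 0+0i
  Re(fft(X, inverse = TRUE)) / N
}

#' Lilliefors null distribution of the KS statistic
#'
#' The Kolmogorov-Smirnov statistic of a standardized normal sample against
#' the fitted normal is distribution-free given `n`, so its null can be
#' simulated once and reused.
#'
#' @param n sample size.
#' @param n_mc Monte-Carlo replicates (>= 2000 recommended).
#' @param seed integer.
#' @return sorted numeric vector of null statistics.
#' @export
lilliefors_null <- function(n, n_mc = 2000L, seed = 1L) {
  with_seed(seed, {
    sort(vapply(seq_len(n_mc), function(i) lilliefors_stat(rnorm(n)), 0))
  })
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  u <- pnorm(z)
  max(seq_len(n) / n - u, u - (seq_len(n) - 1L) / n)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS distance between the sample and a normal with estimated mean/SD, with
#' the p-value taken from a Monte-Carlo simulation of the parameter-free
#' null (never from the standard KS tables, which are wrong when parameters
#' are estimated).
#'
#' @param x numeric sample (>= 4 observations, non-constant).
#' @param n_mc null replicates when `null_stats` is not supplied.
#' @param seed seed for the on-the-fly null simulation.
#' @param null_stats optional precomputed [lilliefors_null()] table for
#'   `length(x)`.
#' @return list `statistic`, `p`.
#' @export
lilliefors_test <- function(x, n_mc = 2000L, seed = 1L, null_stats = NULL) {
  if (length(x) < 4L) stop("need >= 4 observations", call. = FALSE)
  if (sd(x) == 0) stop("Lilliefors statistic undefined for constant sample",
                       call. = FALSE)
  D <- lilliefors_stat(x)
  if (is.null(null_stats)) null_stats <- lilliefors_null(length(x), n_mc, seed)
  p <- (1 + sum(null_stats >= D)) / (length(null_stats) + 1)
  list(statistic = D, p = p)
}

#' Mann-Whitney U test with normal approximation
#'
#' Mid-ranks for ties, tie-corrected variance, continuity correction, and a
#' two-sided p-value from the normal approximation — reported with the Z
#' statistic, as is conventional in clinical reporting.
#'
#' @param x,y numeric samples.
#' @return list `U` (for `x`), `Z`, `p`, `mean_x`, `mean_y`, `sd_x`, `sd_y`.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  if (sigma2 <= 0) {
    Z <- 0; p <- 1    # all observations tied
  } else {
    cc <- if (U == mu) 0 else 0.5
    Z <- (U - mu - sign(U - mu) * cc) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(Z))
    p <- min(p, 1)
  }
  list(U = U, Z = Z, p = p, mean_x = mean(x), mean_y = mean(y),
       sd_x = sd(x), sd_y = sd(y))
}

#' Compare note polarity between two groups
#'
#' Normality is screened per group with the Lilliefors-corrected KS test,
#' then the groups are compared with the Mann-Whitney U test.
#'
#' @param polarities_by_group named list of two numeric vectors (>= 8
#'   observations each).
#' @param n_mc Lilliefors null replicates.
#' @param seed integer.
#' @return list `ks_lilliefors` (per group: statistic + p, or a constant-
#'   sample flag), `mann_whitney`, `groups`.
#' @export
compare_groups <- function(polarities_by_group, n_mc = 2000L, seed = 1L) {
  stopifnot(length(polarities_by_group) == 2L)
  if (any(vapply(polarities_by_group, length, 0L) < 8L)) {
    stop("each group needs >= 8 observations", call. = FALSE)
  }
  gnames <- names(polarities_by_group)
  ks <- lapply(seq_along(polarities_by_group), function(i) {
    x <- polarities_by_group[[i]]
    if (sd(x) == 0) {
      list(statistic = NA_real_, p = NA_real_, constant_sample = TRUE)
    } else {
      c(lilliefors_test(x, n_mc = n_mc,
                        seed = derive_seed(seed, paste0("lillie_", i))),
        constant_sample = FALSE)
    }
  })
  names(ks) <- gnames
  mw <- mann_whitney(polarities_by_group[[1]], polarities_by_group[[2]])
  list(ks_lilliefors = ks, mann_whitney = mw, groups = gnames)
}
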