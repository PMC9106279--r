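# Shared fixtures and independent test oracles.

FIX <- fixture_lexicons()
PCONF <- polarity_config()

small_corpus <- function(seed = 7L, ...) {
  generate_corpus(synth_config(seed = seed, ...))
}

# Brute-force DTW: enumerate every monotone warping path recursively and
# take the minimum accumulated squared cost; independent of the DP code.
dtw_brute <- function(a, b) {
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (a[i] - b[j])^2
    if (acc >= best) return(invisible(NULL))
    if (i == length(a) && j == length(b)) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < length(a) && j < length(b)) walk(i + 1, j + 1, acc)
    if (i < length(a)) walk(i + 1, j, acc)
    if (j < length(b)) walk(i, j + 1, acc)
  }
  walk(1, 1, 0)
  sqrt(best) / (length(a) + length(b))
}

# Exhaustive pairwise-comparison AUC: fraction of (positive, negative)
# pairs where the positive scores higher, ties counting one half.
auc_pairwise <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Random sentence maker for polarity property tests: mixes anchors,
# shifters, neutral fillers and commas.
random_sentence <- function(n_tokens) {
  pool <- c(names(FIX$binary$entries)[1:8], names(FIX$shifter$entries),
            sprintf("f%02d", 1:10), ",")
  tokens <- sample(pool, n_tokens, replace = TRUE)
  if (all(tokens == ",")) tokens[1] <- "f01"
  tokens
}

expect_rows_sum_to_one <- function(m, tol = 1e-9) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
}

# Perfectly separable two-group corpus (disjoint group vocabularies).
planted_dtm <- function(n_per = 60L, seed = 51L) {
  set.seed(seed)
  mk <- function(id, lem) structure(
    list(note_id = id, sentences = list(lem), lemmas = list(lem),
         content_lemmas = list(lem)), class = "notepol_tokenized_note")
  toks <- c(
    lapply(seq_len(n_per), function(i)
      mk(paste0("c", i), sample(sprintf("cv%02d", 1:15), 20, replace = TRUE))),
    lapply(seq_len(n_per), function(i)
      mk(paste0("n", i), sample(sprintf("nc%02d", 1:15), 20, replace = TRUE))))
  build_dtm(toks, rep(c("covid", "non_covid"), each = n_per))
}
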