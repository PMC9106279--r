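test_that("config validation catches bad simplexes and date ranges", {
  expect_error(synth_config(date_range = c("2020-01-01", "2020-01-20")),
               "2 calendar months")
  expect_error(synth_config(date_range = c("2020-03-01", "2020-01-01")),
               "start <= end")
  expect_error(synth_config(sentiment_mix = list(
    covid = c(positive = 0.9, negative = 0.3, neutral = 0.2),
    non_covid = c(positive = 0.4, negative = 0.4, neutral = 0.2))),
    "simplex")
  expect_error(synth_config(prevalence_shift = list(covid = matrix(1, 2, 2))),
               "prevalence_shift")
})

test_that("fixed seed gives a byte-identical corpus; zero rate gives no duplicates", {
  a <- small_corpus(seed = 7L, n_patients = 4L,
                    date_range = c("2020-01-01", "2020-02-10"))
  b <- small_corpus(seed = 7L, n_patients = 4L,
                    date_range = c("2020-01-01", "2020-02-10"))
  expect_identical(a$notes, b$notes)
  expect_identical(a$truth$true_topic_word, b$truth$true_topic_word)
  z <- generate_corpus(synth_config(seed = 3L, duplicate_rate = 0,
                                    n_patients = 3L))
  expect_length(z$truth$duplicate_ids, 0L)
})

test_that("generated notes respect metadata contracts and duplicate bookkeeping", {
  cc <- small_corpus(seed = 11L, n_patients = 6L, duplicate_rate = 0.1)
  notes <- cc$notes
  expect_true(all(notes$shift %in% c("morning", "afternoon", "night")))
  expect_true(all(notes$group %in% c("covid", "non_covid")))
  expect_true(!anyDuplicated(notes$note_id))
  rng <- as.Date(c("2020-01-01", "2020-03-30"))
  expect_true(all(notes$date >= rng[1] & notes$date <= rng[2] + 1))
  # duplicate count is exactly round(rate * N) and copies are verbatim,
  # same patient
  N <- nrow(notes)
  expect_identical(length(cc$truth$duplicate_ids), as.integer(round(0.1 * N)))
  for (i in seq_along(cc$truth$duplicate_ids)) {
    d <- notes[note_id == cc$truth$duplicate_ids[i]]
    s <- notes[note_id == cc$truth$duplicate_source_ids[i]]
    expect_identical(d$text, s$text)
    expect_identical(d$patient_id, s$patient_id)
  }
  expect_rows_sum_to_one(cc$truth$true_topic_word)
  expect_rows_sum_to_one(cc$truth$true_doc_topic)
})

test_that("sentiment emission fractions obey the configured mix (LLN)", {
  cc <- generate_corpus(synth_config(
    seed = 5L, n_patients = 12L,
    date_range = c("2020-01-01", "2020-03-30"),
    sentiment_mix = list(covid = c(positive = 0.6, negative = 0.2, neutral = 0.2),
                         non_covid = c(positive = 0.3, negative = 0.5, neutral = 0.2)),
    duplicate_rate = 0, polarity_truth = FALSE))
  em <- cc$truth$sentiment_emissions
  expect_gt(sum(em["covid", ]), 1500)   # enough emissions for the LLN band
  expect_equal(em["covid", "positive"] / sum(em["covid", ]), 0.6,
               tolerance = 0.05)
  expect_equal(em["non_covid", "negative"] / sum(em["non_covid", ]), 0.5,
               tolerance = 0.05)
})

test_that("empirical topic-word distributions converge to truth as N grows", {
  tv_at <- function(n_pat) {
    cc <- generate_corpus(synth_config(seed = 13L, n_patients = n_pat,
                                       duplicate_rate = 0,
                                       polarity_truth = FALSE))
    z <- unlist(cc$truth$token_topics)
    w <- unlist(cc$truth$token_words)
    K <- nrow(cc$truth$true_topic_word)
    emp <- matrix(0, K, length(cc$truth$topic_vocab),
                  dimnames = list(NULL, cc$truth$topic_vocab))
    tb <- table(z, factor(w, levels = cc$truth$topic_vocab))
    emp[as.integer(rownames(tb)), ] <- as.matrix(tb)
    emp <- emp / pmax(rowSums(emp), 1)
    mean(0.5 * rowSums(abs(emp - cc$truth$true_topic_word)))
  }
  tv_small <- tv_at(2L)
  tv_large <- tv_at(16L)
  expect_lt(tv_large, tv_small)
  expect_lt(tv_large, 0.12)
})

test_that("polarity fixture grid covers the factorial design with oracle deltas", {
  fx <- build_polarity_fixtures()
  expect_gte(nrow(fx), 288L)
  expect_identical(nrow(unique(fx[, .(n_neg, n_amp, n_deamp, comma, p, length)])),
                   nrow(fx))
  # no polarized word -> delta 0 (strip the anchor from a fixture sentence)
  toks <- setdiff(fx$tokens[[1]], c("contento", "triste"))
  expect_identical(notepol:::oracle_delta(toks, FIX$binary, FIX$shifter), 0)
  # single negator with a +1 anchor reverses the sign
  neg_cases <- fx[n_neg == 1 & n_amp == 0 & n_deamp == 0 & comma == FALSE & p == 1]
  expect_true(all(neg_cases$delta < 0))
})

test_that("write_corpus emits readable CSV and truth JSON", {
  cc <- small_corpus(seed = 2L, n_patients = 2L, polarity_truth = FALSE)
  d <- withr::local_tempdir()
  paths <- write_corpus(cc, d)
  back <- read_notes(paths["notes"])
  expect_identical(nrow(back), nrow(cc$notes))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_setequal(truth$duplicate_ids, cc$truth$duplicate_ids)
})
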