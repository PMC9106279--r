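#' Configuration for the synthetic note generator
#'
#' The generator emulates the structure of a shift-based nursing-note corpus:
#' two patient groups (a COVID ward and a non-COVID ward), up to three notes
#' per patient per day in distinct work shifts (morning / afternoon / night),
#' a span of at least two calendar months, note text drawn from an LDA
#' process over an abstract topic vocabulary, one sentiment-bearing emission
#' per sentence (positive / negative / neutral word, per-group mix), valence
#' shifters injected in front of sentiment words, interspersed stopwords and
#' commas, and verbatim copy-paste duplicates.
#'
#' @param n_patients number of patients.
#' @param notes_per_patient_per_day notes per patient per day (1-3, each in
#'   a distinct randomly chosen shift).
#' @param date_range length-2 character/Date vector (ISO dates) spanning at
#'   least two calendar months.
#' @param group_split fraction of patients labelled `covid`.
#' @param n_topics_true true topic count K*.
#' @param vocab_size size of the topic-word vocabulary (disjoint from
#'   sentiment words, shifters and stopwords).
#' @param dirichlet_doc_alpha,dirichlet_topic_beta symmetric Dirichlet
#'   concentrations of the document-topic and topic-word priors.
#' @param sentiment_mix named list `covid`/`non_covid`, each a 3-simplex
#'   `c(positive=, negative=, neutral=)`: per-sentence emission mix.
#' @param shifter_rate probability that a sentiment emission is preceded by
#'   a valence shifter (role drawn uniformly).
#' @param duplicate_rate fraction of the final corpus that is injected
#'   verbatim duplicates of earlier notes from the same patient.
#' @param prevalence_shift `NULL`, or named list `covid`/`non_covid` of
#'   months-in-range x K* matrices of multiplicative tilts applied to the
#'   document Dirichlet prior (rows follow the calendar months in range).
#' @param comma_rate probability a sentence carries an interior comma token.
#' @param stopword_max max stopwords interspersed per sentence (0 to this,
#'   uniform).
#' @param sentences_per_note,sentence_len integer ranges (length-2) for note
#'   and sentence sizes; defaults 1-6 sentences of 3-15 topic tokens.
#' @param polarity_truth compute the analytic polarity of every generated
#'   sentence with the brute-force oracle (slower; default `TRUE`).
#' @param seed integer seed; the corpus is a pure function of the config.
#' @return validated config object of class `notepol_synth_config`.
#' @export
synth_config <- function(n_patients = 10L,
                         notes_per_patient_per_day = 1L,
                         date_range = c("2020-01-01", "2020-03-30"),
                         group_split = 0.5,
                         n_topics_true = 5L,
                         vocab_size = 100L,
                         dirichlet_doc_alpha = 0.3,
                         dirichlet_topic_beta = 0.05,
                         sentiment_mix = list(
                           covid     = c(positive = 0.5, negative = 0.3, neutral = 0.2),
                           non_covid = c(positive = 0.4, negative = 0.4, neutral = 0.2)),
                         shifter_rate = 0.25,
                         duplicate_rate = 0.1,
                         prevalence_shift = NULL,
                         comma_rate = 0.1,
                         stopword_max = 3L,
                         sentences_per_note = c(1L, 6L),
                         sentence_len = c(3L, 15L),
                         polarity_truth = TRUE,
                         seed = 1L) {
  dates <- as.Date(date_range)
  if (any(is.na(dates)) || length(dates) != 2L || dates[2] < dates[1]) {
    stop("date_range must be two ISO dates, start <= end", call. = FALSE)
  }
  months <- unique(format(seq(dates[1], dates[2], by = "day"), "%Y-%m"))
  if (length(months) < 2L) {
    stop("date_range must span at least 2 calendar months", call. = FALSE)
  }
  stopifnot(n_patients >= 1L,
            notes_per_patient_per_day >= 1L, notes_per_patient_per_day <= 3L,
            group_split >= 0, group_split <= 1,
            n_topics_true >= 2L, vocab_size >= n_topics_true,
            dirichlet_doc_alpha > 0, dirichlet_topic_beta > 0,
            shifter_rate >= 0, shifter_rate <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            comma_rate >= 0, comma_rate <= 1)
  if (!setequal(names(sentiment_mix), GROUPS)) {
    stop("sentiment_mix must have entries 'covid' and 'non_covid'", call. = FALSE)
  }
  for (g in GROUPS) {
    mix <- sentiment_mix[[g]]
    if (!setequal(names(mix), c("positive", "negative", "neutral"))) {
      stop("sentiment_mix[['", g, "']] needs names positive/negative/neutral",
           call. = FALSE)
    }
    check_simplex(unname(mix), paste0("sentiment_mix[['", g, "']]"))
  }
  if (!is.null(prevalence_shift)) {
    for (g in names(prevalence_shift)) {
      m <- prevalence_shift[[g]]
      if (!is.matrix(m) || nrow(m) != length(months) || ncol(m) != n_topics_true ||
          any(m <= 0)) {
        stop("prevalence_shift[['", g, "']] must be a positive ",
             length(months), " x ", n_topics_true, " matrix", call. = FALSE)
      }
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    notes_per_patient_per_day = as.integer(notes_per_patient_per_day),
    date_range = dates, months = months,
    group_split = group_split,
    n_topics_true = as.integer(n_topics_true),
    vocab_size = as.integer(vocab_size),
    dirichlet_doc_alpha = dirichlet_doc_alpha,
    dirichlet_topic_beta = dirichlet_topic_beta,
    sentiment_mix = lapply(sentiment_mix, function(m)
      m[c("positive", "negative", "neutral")]),
    shifter_rate = shifter_rate,
    duplicate_rate = duplicate_rate,
    prevalence_shift = prevalence_shift,
    comma_rate = comma_rate,
    stopword_max = as.integer(stopword_max),
    sentences_per_note = as.integer(sentences_per_note),
    sentence_len = as.integer(sentence_len),
    polarity_truth = isTRUE(polarity_truth),
    seed = as.integer(seed)
  ), class = "notepol_synth_config")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[1] <- 1     # degenerate underflow guard
  x / sum(x)
}

# Token pools for the non-topic vocabulary; must stay inside the fixture
# lexicons (sentiment/shifters) or the fixture stopword list.
.synth_pools <- function() {
  list(
    positive = sprintf("pos%02d", 1:12),
    negative = sprintf("neg%02d", 1:12),
    neutral  = sprintf("neu%02d", 1:8),
    negator = c("no", "nunca", "tampoco"),
    amplifier = c("muy", "mucho", "bastante"),
    deamplifier = c("poco", "apenas", "algo"),
    stopword = c("el", "la", "de", "y", "en", "se", "con", "por")
  )
}

#' Generate a synthetic note corpus with ground truth
#'
#' Deterministic for a fixed config (including its seed): the same config
#' yields a byte-identical corpus and truth. The injected duplicate count is
#' exactly `round(duplicate_rate * N)` where `N` is the total corpus size;
#' duplicates copy the raw text and metadata of a same-patient source note,
#' with a fresh note id and the timestamp advanced by one shift.
#'
#' @param config a [synth_config()].
#' @return list with `notes` (data.table: note_id, patient_id, group, shift,
#'   date, text) and `truth` (class `notepol_ground_truth`): `true_topic_word`
#'   (K* x V row-stochastic), `true_doc_topic` (per-note theta),
#'   `sentences` (note_id, sentence_index, tokens, delta when
#'   `polarity_truth`), `duplicate_ids`, `duplicate_source_ids`,
#'   `sentiment_emissions` (group x category counts), `sentence_counts`
#'   (per note), `topic_vocab`, and per-token topic assignments
#'   `token_topics`/`token_words` for convergence checks.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "notepol_synth_config"))
  cfg <- config
  with_seed(cfg$seed, {
    pools <- .synth_pools()
    K <- cfg$n_topics_true
    V <- cfg$vocab_size
    topic_vocab <- sprintf("w%04d", seq_len(V))
    beta <- t(vapply(seq_len(K), function(k)
      rdirichlet1(rep(cfg$dirichlet_topic_beta, V)), numeric(V)))
    rownames(beta) <- paste0("topic", seq_len(K))
    colnames(beta) <- topic_vocab

    n_cov <- round(cfg$group_split * cfg$n_patients)
    patient_group <- c(rep("covid", n_cov),
                       rep("non_covid", cfg$n_patients - n_cov))
    patient_id <- sprintf("p%03d", seq_len(cfg$n_patients))
    days <- seq(cfg$date_range[1], cfg$date_range[2], by = "day")

    base <- list(); sent_rec <- list()
    theta_all <- list()
    emis <- matrix(0L, 2, 3, dimnames = list(GROUPS,
                                             c("positive", "negative", "neutral")))
    tok_topics <- list(); tok_words <- list()
    note_i <- 0L
    for (pi in seq_len(cfg$n_patients)) {
      grp <- patient_group[pi]
      for (d in seq_along(days)) {
        shifts <- sample(SHIFTS, cfg$notes_per_patient_per_day)
        mon <- match(format(days[d], "%Y-%m"), cfg$months)
        alpha_d <- rep(cfg$dirichlet_doc_alpha, K)
        if (!is.null(cfg$prevalence_shift) &&
            !is.null(cfg$prevalence_shift[[grp]])) {
          alpha_d <- alpha_d * cfg$prevalence_shift[[grp]][mon, ]
        }
        for (sh in shifts) {
          note_i <- note_i + 1L
          nid <- sprintf("n%06d", note_i)
          theta <- rdirichlet1(alpha_d)
          n_sent <- sample(cfg$sentences_per_note[1]:cfg$sentences_per_note[2], 1L)
          sent_tokens <- vector("list", n_sent)
          for (si in seq_len(n_sent)) {
            L <- sample(cfg$sentence_len[1]:cfg$sentence_len[2], 1L)
            z <- sample.int(K, L, replace = TRUE, prob = theta)
            w <- vapply(z, function(k)
              topic_vocab[sample.int(V, 1L, prob = beta[k, ])], "")
            tok_topics[[length(tok_topics) + 1L]] <- z
            tok_words[[length(tok_words) + 1L]] <- w
            # one sentiment emission per sentence
            cat_ <- sample(c("positive", "negative", "neutral"), 1L,
                           prob = cfg$sentiment_mix[[grp]])
            emis[grp, cat_] <- emis[grp, cat_] + 1L
            emission <- sample(pools[[cat_]], 1L)
            if (runif(1) < cfg$shifter_rate) {
              role <- sample(c("negator", "amplifier", "deamplifier"), 1L)
              emission <- c(sample(pools[[role]], 1L), emission)
            }
            pos <- sample.int(L + 1L, 1L) - 1L
            toks <- append(w, emission, after = pos)
            n_stop <- sample.int(cfg$stopword_max + 1L, 1L) - 1L
            if (n_stop > 0L) {
              for (s in sample(pools$stopword, n_stop, replace = TRUE)) {
                toks <- append(toks, s, after = sample.int(length(toks) + 1L, 1L) - 1L)
              }
            }
            if (length(toks) >= 3L && runif(1) < cfg$comma_rate) {
              toks <- append(toks, ",", after = sample.int(length(toks) - 1L, 1L))
            }
            sent_tokens[[si]] <- toks
          }
          base[[note_i]] <- list(note_id = nid, patient_id = patient_id[pi],
                                 group = grp, shift = sh,
                                 date = days[d],
                                 text = paste(vapply(sent_tokens, paste, "",
                                                     collapse = " "),
                                              collapse = " . "))
          theta_all[[note_i]] <- theta
          sent_rec[[note_i]] <- sent_tokens
        }
      }
    }

    n_base <- note_i
    # exact duplicate count: d = round(rate * (n_base + d)), searched locally
    d0 <- round(cfg$duplicate_rate * n_base / (1 - cfg$duplicate_rate))
    cand <- pmax(0L, d0 + (-2:2))
    exact <- cand[cand == round(cfg$duplicate_rate * (n_base + cand))]
    n_dup <- if (length(exact)) exact[1L] else
      cand[which.min(abs(cand - cfg$duplicate_rate * (n_base + cand)))]

    dup_ids <- character(0); dup_src <- character(0)
    if (n_dup > 0L) {
      src_idx <- sample.int(n_base, n_dup, replace = n_dup > n_base)
      for (j in seq_len(n_dup)) {
        note_i <- note_i + 1L
        src <- base[[src_idx[j]]]
        nid <- sprintf("n%06d", note_i)
        sh_i <- match(src$shift, SHIFTS)
        new_shift <- SHIFTS[sh_i %% 3L + 1L]
        new_date <- src$date + (sh_i == 3L)   # night wraps to next morning
        base[[note_i]] <- list(note_id = nid, patient_id = src$patient_id,
                               group = src$group, shift = new_shift,
                               date = new_date, text = src$text)
        theta_all[[note_i]] <- theta_all[[src_idx[j]]]
        sent_rec[[note_i]] <- sent_rec[[src_idx[j]]]
        dup_ids <- c(dup_ids, nid)
        dup_src <- c(dup_src, src$note_id)
      }
    }

    notes <- data.table::rbindlist(base)
    notes[, date := as.Date(date, origin = "1970-01-01")]

    sentences <- data.table::data.table(
      note_id = rep(notes$note_id, lengths(sent_rec)),
      sentence_index = unlist(lapply(sent_rec, seq_along)),
      tokens = unlist(sent_rec, recursive = FALSE)
    )
    if (cfg$polarity_truth) {
      lex <- fixture_lexicons()
      sentences[, delta := vapply(tokens, oracle_delta, 0,
                                  binary_lexicon = lex$binary,
                                  shifter_lexicon = lex$shifter)]
    }

    truth <- structure(list(
      true_topic_word = beta,
      true_doc_topic = do.call(rbind, theta_all),
      sentences = sentences,
      duplicate_ids = dup_ids,
      duplicate_source_ids = dup_src,
      sentiment_emissions = emis,
      sentence_counts = lengths(sent_rec),
      topic_vocab = topic_vocab,
      token_topics = tok_topics,
      token_words = tok_words
    ), class = "notepol_ground_truth")
    rownames(truth$true_doc_topic) <- notes$note_id

    list(notes = notes, truth = truth)
  })
}

#' Generate a plain LDA bag-of-words corpus
#'
#' Pure LDA generative process (no sentences, sentiment or metadata) used
#' for topic-recovery benchmarks: `D` documents of `doc_len` tokens over a
#' `V`-word vocabulary with `K` topics and symmetric Dirichlet priors.
#'
#' @param K,V,D,doc_len corpus dimensions.
#' @param alpha,eta document-topic and topic-word Dirichlet concentrations.
#' @param seed integer.
#' @return list `docs` (list of integer word-id vectors), `beta` (K x V),
#'   `theta` (D x K), `vocab`.
#' @export
generate_lda_corpus <- function(K = 5L, V = 200L, D = 400L, doc_len = 60L,
                                alpha = 0.1, eta = 0.01, seed = 1L) {
  with_seed(seed, {
    beta <- t(vapply(seq_len(K), function(k) rdirichlet1(rep(eta, V)),
                     numeric(V)))
    theta <- t(vapply(seq_len(D), function(d) rdirichlet1(rep(alpha, K)),
                      numeric(K)))
    docs <- lapply(seq_len(D), function(d) {
      z <- sample.int(K, doc_len, replace = TRUE, prob = theta[d, ])
      vapply(z, function(k) sample.int(V, 1L, prob = beta[k, ]), 1L)
    })
    list(docs = docs, beta = beta, theta = theta,
         vocab = sprintf("w%04d", seq_len(V)))
  })
}

#' Exhaustive polarity fixture grid
#'
#' Builds template sentences over the full factorial grid 0-2 negators x
#' 0-2 amplifiers x 0-2 deamplifiers x comma present/absent x anchor
#' polarity +1/-1 x target sentence length \{4, 7, 10\} (324 cases), with
#' the expected polarity of each computed by the independent straight-line
#' oracle. Shifters sit immediately before the anchor; a comma (when
#' present) follows the first shifter, or directly precedes the anchor when
#' there are no shifters; one neutral pad follows the anchor, the rest lead.
#'
#' @param lexicons list as returned by [fixture_lexicons()] (default).
#' @param config a [polarity_config()] forwarded to the oracle.
#' @return data.table with columns n_neg, n_amp, n_deamp, comma, p, length,
#'   tokens (list column), delta.
#' @export
build_polarity_fixtures <- function(lexicons = fixture_lexicons(),
                                    config = polarity_config()) {
  negs <- c("no", "nunca"); amps <- c("muy", "mucho")
  deamps <- c("poco", "apenas")
  grid <- expand.grid(n_neg = 0:2, n_amp = 0:2, n_deamp = 0:2,
                      comma = c(FALSE, TRUE), p = c(1, -1),
                      length = c(4L, 7L, 10L))
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    shifters <- c(head(negs, g$n_neg), head(amps, g$n_amp),
                  head(deamps, g$n_deamp))
    anchor <- if (g$p > 0) "contento" else "triste"
    m <- length(shifters)
    pads <- max(0L, g$length - m - 1L)
    pad_back <- min(1L, pads)
    pad_front <- pads - pad_back
    fillers <- sprintf("x%02d", seq_len(pads))
    toks <- c(head(fillers, pad_front), shifters, anchor,
              tail(fillers, pad_back))
    if (g$comma) {
      at <- if (m > 0L) pad_front + 1L else pad_front
      toks <- append(toks, ",", after = at)
    }
    rows[[r]] <- list(n_neg = g$n_neg, n_amp = g$n_amp, n_deamp = g$n_deamp,
                      comma = g$comma, p = g$p, length = g$length,
                      tokens = list(toks),
                      delta = oracle_delta(
                        toks, lexicons$binary, lexicons$shifter,
                        before = config$before, after = config$after,
                        c_weight = config$c, deamp_floor = config$deamp_floor,
                        comma_truncation = config$comma_truncation))
  }
  data.table::rbindlist(rows)
}

#' Write a synthetic corpus to disk
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if missing).
#' @return paths of the written files (notes CSV + truth JSON), invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  notes_path <- file.path(dir, "notes.csv")
  data.table::fwrite(corpus$notes, notes_path)
  truth_path <- file.path(dir, "truth.json")
  tr <- corpus$truth
  jsonlite::write_json(list(
    duplicate_ids = tr$duplicate_ids,
    duplicate_source_ids = tr$duplicate_source_ids,
    sentiment_emissions = as.data.frame(tr$sentiment_emissions),
    true_topic_word = tr$true_topic_word,
    true_doc_topic = tr$true_doc_topic,
    sentence_counts = tr$sentence_counts
  ), truth_path, digits = NA)
  invisible(c(notes = notes_path, truth = truth_path))
}
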