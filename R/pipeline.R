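#' Default pipeline configuration
#'
#' One configuration object drives the whole pipeline. Defaults run every
#' stage on a synthetic corpus; pointing `notes` at a CSV skips synthesis.
#' Stage parameters are grouped by stage; every stochastic stage derives a
#' named substream from `seed` (see [derive_seed()]), so no stage consumes
#' another's random numbers.
#'
#' @param out_dir run directory.
#' @param seed global seed.
#' @param notes optional path to an existing note CSV (disables synth).
#' @param lexicon_paths named list (emotion/valence/binary/shifter TSV
#'   paths); defaults to the packaged fixtures.
#' @param lemma_table,stopwords paths (defaults: packaged fixtures).
#' @param stages character subset of
#'   `c("synth", "preprocess", "sentiment", "polarity", "temporal",
#'   "topics", "classify")`.
#' @param synth list of [synth_config()] overrides.
#' @param polarity list of [polarity_config()] overrides.
#' @param topics list: `k_grid`, `eta`, `n_iter`, `burn_in`, `thin`, `M`,
#'   `n_perm`, `cor_threshold`.
#' @param classify list: `train_frac`.
#' @param dedup_scope `"patient"` or `"corpus"`.
#' @return `notepol_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, notes = NULL,
                            lexicon_paths = NULL, lemma_table = NULL,
                            stopwords = NULL,
                            stages = c("synth", "preprocess", "sentiment",
                                       "polarity", "temporal", "topics",
                                       "classify"),
                            synth = list(), polarity = list(),
                            topics = list(), classify = list(),
                            dedup_scope = "patient") {
  topics_def <- list(k_grid = 4:6, eta = 0.01, n_iter = 200L, burn_in = 100L,
                     thin = 5L, M = 10L, n_perm = 199L, cor_threshold = 0.3)
  topics <- utils::modifyList(topics_def, topics)
  classify <- utils::modifyList(list(train_frac = 0.75), classify)
  structure(list(out_dir = out_dir, seed = as.integer(seed), notes = notes,
                 lexicon_paths = lexicon_paths, lemma_table = lemma_table,
                 stopwords = stopwords, stages = stages, synth = synth,
                 polarity = polarity, topics = topics, classify = classify,
                 dedup_scope = dedup_scope),
            class = "notepol_pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @param out_dir,seed optional overrides of the file's values.
#' @return `notepol_pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (!is.null(seed)) raw$seed <- seed
  if (is.null(raw$out_dir)) stop("config needs out_dir", call. = FALSE)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

stage_log <- function(run, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  cat(line, "\n", file = file.path(run, "run.log"), append = TRUE)
}

#' Run the note-analysis pipeline
#'
#' Executes the enabled stages in order (synth, preprocess, sentiment,
#' polarity, temporal, topics, classify), writing each stage's CSV/JSON
#' outputs plus `manifest.json` (seeds, input and output hashes, package
#' version). A stage failure aborts downstream stages; partial outputs are
#' kept and a `FAILED` marker file names the failing stage. Reruns with the
#' same config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `status` (`"ok"`/`"failed"`), `failed_stage`
#'   (or `NULL`), `out_dir`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "notepol_pipeline_config"))
  run <- config$out_dir
  dir.create(run, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(run, c("run.log", "FAILED")))
  seed <- config$seed
  seeds <- list()
  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  failed <- NULL

  lex <- if (is.null(config$lexicon_paths)) fixture_lexicons() else list(
    emotion = read_lexicon(config$lexicon_paths$emotion, "emotion"),
    valence = read_lexicon(config$lexicon_paths$valence, "valence"),
    binary = read_lexicon(config$lexicon_paths$binary, "binary"),
    shifter = read_lexicon(config$lexicon_paths$shifter, "shifter"))
  lemma_tab <- if (is.null(config$lemma_table)) character(0) else
    read_lemma_table(config$lemma_table)
  stops <- if (is.null(config$stopwords)) character(0) else
    read_stopwords(config$stopwords)

  stages <- list(
    synth = function() {
      if (!is.null(config$notes)) {
        state$notes <- read_notes(config$notes)
        stage_log(run, "synth", "skipped: external notes supplied")
        return(invisible(NULL))
      }
      seeds$synth <<- derive_seed(seed, "synth")
      sc <- do.call(synth_config,
                    utils::modifyList(config$synth, list(seed = seeds$synth)))
      corpus <- generate_corpus(sc)
      state$notes <- corpus$notes
      state$truth <- corpus$truth
      outputs <<- c(outputs, write_corpus(corpus, run))
      stage_log(run, "synth", sprintf("%d notes generated", nrow(corpus$notes)))
    },
    preprocess = function() {
      dd <- deduplicate(state$notes, scope = config$dedup_scope)
      state$notes <- dd$kept
      state$toks <- preprocess_corpus(dd$kept, lemma_tab, stops)
      p <- file.path(run, "notes_dedup.csv")
      data.table::fwrite(dd$kept, p)
      outputs <<- c(outputs, p)
      stage_log(run, "preprocess",
                sprintf("%d duplicates removed, %d notes kept",
                        dd$removed, nrow(dd$kept)))
    },
    sentiment = function() {
      state$profiles <- lapply(state$toks, score_note, lexicons = lex)
      gt <- group_table(state$profiles, state$notes$group)
      tidy <- sentiment_tidy(gt)
      p1 <- file.path(run, "sentiment_table.csv")
      data.table::fwrite(tidy, p1)
      tests <- lapply(gt, function(e) e$chi_square[c("statistic", "df", "p")])
      p2 <- file.path(run, "sentiment_tests.json")
      jsonlite::write_json(tests, p2, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, p1, p2)
      stage_log(run, "sentiment", "group tables + chi-square written")
    },
    polarity = function() {
      pc <- do.call(polarity_config, config$polarity)
      sent <- polarity_corpus(state$toks, lex$binary, lex$shifter, pc)
      state$sentence_polarity <- sent
      state$note_polarity <- sent[, .(delta = note_polarity(delta)), by = note_id]
      p1 <- file.path(run, "polarity_sentences.csv")
      data.table::fwrite(sent, p1)
      by_group <- split(state$note_polarity$delta,
                        state$notes$group[match(state$note_polarity$note_id,
                                                state$notes$note_id)])
      seeds$polarity <<- derive_seed(seed, "polarity")
      cmp <- compare_groups(by_group, seed = seeds$polarity)
      p2 <- file.path(run, "polarity_comparison.json")
      jsonlite::write_json(cmp, p2, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      outputs <<- c(outputs, p1, p2)
      stage_log(run, "polarity",
                sprintf("Mann-Whitney Z = %.3f", cmp$mann_whitney$Z))
    },
    temporal = function() {
      ser <- monthly_series(state$notes, profiles = state$profiles,
                            note_deltas = state$note_polarity)
      long <- data.table::rbindlist(lapply(ser, function(s)
        data.table::data.table(group = s$group, dictionary = s$dictionary,
                               category = s$category, month = s$months,
                               value = s$values)))
      p1 <- file.path(run, "monthly_series.csv")
      data.table::fwrite(long, p1)
      # distance between the two groups per dictionary/category
      key <- vapply(ser, function(s) paste(s$dictionary, s$category, sep = "/"), "")
      rows <- list()
      for (kk in unique(key)) {
        pair <- ser[key == kk]
        if (length(pair) == 2L) {
          rows[[kk]] <- data.table::data.table(
            dictionary = pair[[1]]$dictionary, category = pair[[1]]$category,
            dtw = dtw_distance(pair[[1]], pair[[2]]))
        }
      }
      p2 <- file.path(run, "dtw_distances.csv")
      data.table::fwrite(data.table::rbindlist(rows), p2)
      outputs <<- c(outputs, p1, p2)
      stage_log(run, "temporal", sprintf("%d series, %d DTW pairs",
                                         length(ser), length(rows)))
    },
    topics = function() {
      docs <- lapply(state$toks, function(tk)
        unlist(tk$content_lemmas, use.names = FALSE))
      keep <- lengths(docs) > 0L
      docs <- docs[keep]
      tc <- config$topics
      seeds$topics <<- derive_seed(seed, "topics")
      diag_ <- select_K(docs, K_grid = tc$k_grid, eta = tc$eta,
                        n_iter = tc$n_iter, burn_in = tc$burn_in,
                        thin = tc$thin, seed = seeds$topics, M = tc$M)
      model <- diag_$models[[as.character(diag_$selected_K)]]
      p1 <- file.path(run, "topic_diagnostics.csv")
      data.table::fwrite(diag_$frontier, p1)
      p2 <- file.path(run, "topic_top_words.csv")
      data.table::fwrite(top_words(model, M = 5L), p2)
      p3 <- file.path(run, "theta_hat.csv")
      data.table::fwrite(data.table::as.data.table(model$theta_hat), p3)
      covs <- data.frame(group = state$notes$group[keep],
                         month = month_index(state$notes$date[keep]))
      seeds$prevalence <<- derive_seed(seed, "prevalence")
      pe <- prevalence_effects(model, covs, n_perm = tc$n_perm,
                               seed = seeds$prevalence,
                               cor_threshold = tc$cor_threshold)
      p4 <- file.path(run, "prevalence_effects.json")
      jsonlite::write_json(list(effects = pe$effects, edges = pe$edges,
                                selected_K = diag_$selected_K),
                           p4, auto_unbox = TRUE, digits = NA)
      p5 <- file.path(run, "topic_network_edges.csv")
      data.table::fwrite(pe$edges, p5)
      outputs <<- c(outputs, p1, p2, p3, p4, p5)
      state$lda <- model
      stage_log(run, "topics", sprintf("selected K = %d", diag_$selected_K))
    },
    classify = function() {
      dtm <- build_dtm(state$toks, state$notes$labels %||% state$notes$group)
      seeds$classify <<- derive_seed(seed, "classify")
      suite <- run_model_suite(dtm, train_frac = config$classify$train_frac,
                               seed = seeds$classify)
      p <- file.path(run, "classifier_metrics.csv")
      data.table::fwrite(suite$table, p)
      outputs <<- c(outputs, p)
      stage_log(run, "classify",
                sprintf("NB accuracy %.3f", suite$table$accuracy[1]))
    })

  enabled <- intersect(names(stages), config$stages)
  # stages that later stages depend on are always run
  if (any(c("preprocess", "sentiment", "polarity", "temporal", "topics",
            "classify") %in% enabled)) {
    enabled <- union(c("synth", "preprocess"), enabled)
  }
  if ("temporal" %in% enabled) {
    enabled <- union(enabled, c("sentiment", "polarity"))
  }
  enabled <- intersect(names(stages), enabled)

  for (st in enabled) {
    res <- tryCatch({ stages[[st]](); NULL }, error = function(e) e)
    if (!is.null(res)) {
      failed <- st
      writeLines(sprintf("stage %s failed: %s", st, conditionMessage(res)),
                 file.path(run, "FAILED"))
      stage_log(run, st, paste("FAILED:", conditionMessage(res)))
      break
    }
  }

  hashes <- tools::md5sum(sort(unique(outputs[file.exists(outputs)])))
  names(hashes) <- basename(names(hashes))
  manifest <- list(package = "notepol",
                   version = as.character(utils::packageVersion("notepol")),
                   seed = seed, stage_seeds = seeds,
                   stages = enabled, failed_stage = failed,
                   dedup_scope = config$dedup_scope,
                   input_notes = if (is.null(config$notes)) NULL else
                     unname(tools::md5sum(config$notes)),
                   output_hashes = as.list(hashes))
  jsonlite::write_json(manifest, file.path(run, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(status = if (is.null(failed)) "ok" else "failed",
                 failed_stage = failed, out_dir = run, manifest = manifest))
}
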