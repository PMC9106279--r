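#' Score a note against the three sentiment lexicons
#'
#' Counts occurrences (with multiplicity) of the note's content lemmas in
#' each lexicon category. A lemma listed under several emotion categories
#' counts once per category (NRC convention).
#'
#' @param tok a `notepol_tokenized_note` with `content_lemmas` available.
#' @param lexicons list with elements `emotion`, `valence`, `binary`
#'   (see [fixture_lexicons()]).
#' @return `notepol_sentiment_profile`: `note_id`, `emotion_counts` (10
#'   categories), `valence_counts` (buckets -5..-1, +1..+5), `binary_counts`
#'   (positive/negative), `matched_tokens` (tokens matching the binary
#'   lexicon).
#' @export
score_note <- function(tok, lexicons) {
  stopifnot(inherits(tok, "notepol_tokenized_note"))
  lem <- unlist(tok$content_lemmas, use.names = FALSE)

  emo <- stats::setNames(integer(length(EMOTION_CATEGORIES)), EMOTION_CATEGORIES)
  hits <- lexicons$emotion$entries[lem[lem %in% names(lexicons$emotion$entries)]]
  for (cats in hits) emo[cats] <- emo[cats] + 1L

  vbuckets <- as.character(c(-5:-1, 1:5))
  val <- stats::setNames(integer(10L), vbuckets)
  vs <- lexicons$valence$entries[lem]
  vs <- vs[!is.na(vs)]
  if (length(vs)) {
    tb <- table(factor(as.character(vs), levels = vbuckets))
    val <- val + as.integer(tb)
    names(val) <- vbuckets
  }

  bs <- lexicons$binary$entries[lem]
  bs <- bs[!is.na(bs)]
  bin <- c(positive = sum(bs > 0), negative = sum(bs < 0))

  structure(list(note_id = tok$note_id, emotion_counts = emo,
                 valence_counts = val, binary_counts = bin,
                 matched_tokens = length(bs)),
            class = "notepol_sentiment_profile")
}

profile_counts <- function(profiles, dictionary) {
  field <- switch(dictionary, nrc = "emotion_counts", afinn = "valence_counts",
                  bing = "binary_counts",
                  stop("unknown dictionary '", dictionary, "'", call. = FALSE))
  do.call(rbind, lapply(profiles, function(p) p[[field]]))
}

# Pearson chi-square on a counts matrix (rows = groups), no continuity
# correction by default; computed natively so tests can cross-check against
# stats::chisq.test as an independent route.
chisq_independence <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("chi-square needs at least a 2x2 table with positive margins",
         call. = FALSE)
  }
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  dev <- abs(counts - E)
  if (yates) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       expected = E, observed = counts)
}

#' Group-level sentiment contingency tables with chi-square tests
#'
#' Builds, per dictionary, the group x category table of raw counts,
#' column-normalized percentages per group, and a Pearson chi-square test
#' of independence on the counts (not the percentages).
#'
#' @param profiles list of sentiment profiles (one per note).
#' @param groups character vector of group labels parallel to `profiles`.
#' @param dictionaries subset of `c("nrc", "afinn", "bing")`.
#' @param yates apply the continuity correction (off by default; tables in
#'   this workflow are large).
#' @return `notepol_group_table`: per dictionary a list with `counts`,
#'   `pct` (rows sum to 100), `chi_square` (statistic, df, p). Groups with
#'   zero matched tokens for a dictionary are excluded with a warning.
#' @export
group_table <- function(profiles, groups,
                        dictionaries = c("nrc", "afinn", "bing"),
                        yates = FALSE) {
  stopifnot(length(profiles) == length(groups))
  if (length(unique(groups)) < 2L) stop("need >= 2 groups", call. = FALSE)
  out <- list()
  for (dict in dictionaries) {
    per_note <- profile_counts(profiles, dict)
    counts <- rowsum(per_note, groups)
    zero <- rowSums(counts) == 0
    if (any(zero)) {
      warning("group(s) with zero matches excluded for ", dict, ": ",
              paste(rownames(counts)[zero], collapse = ", "), call. = FALSE)
      counts <- counts[!zero, , drop = FALSE]
    }
    pct <- sweep(counts, 1, rowSums(counts), "/") * 100
    out[[dict]] <- list(counts = counts, pct = pct,
                        chi_square = chisq_independence(counts, yates = yates))
  }
  structure(out, class = "notepol_group_table")
}

#' Bonferroni post hoc cell tests for a sentiment contingency table
#'
#' Computes the adjusted standardized residual of every cell,
#' \eqn{z = (O - E) / \sqrt{E (1 - r/n)(1 - c/n)}}, and flags a cell as
#' significant when its two-sided normal p-value is below `alpha / m`,
#' where `m` is the number of testable cells. Cells with expected count 0
#' are flagged untestable.
#'
#' @param table_entry one dictionary's entry of a [group_table()] result
#'   (or any list with an `observed`-bearing `chi_square`).
#' @param alpha family-wise level (default 0.05).
#' @return list with matrices `residuals`, `p`, `significant` (logical),
#'   `untestable` (logical), and `m`.
#' @export
posthoc_bonferroni <- function(table_entry, alpha = 0.05) {
  O <- table_entry$chi_square$observed
  E <- table_entry$chi_square$expected
  if (nrow(O) < 2L || ncol(O) < 2L) {
    stop("post hoc residuals need a table with >= 2 rows and columns",
         call. = FALSE)
  }
  n <- sum(O)
  rfrac <- rowSums(O) / n
  cfrac <- colSums(O) / n
  denom <- sqrt(E * outer(1 - rfrac, 1 - cfrac))
  untestable <- E == 0 | denom == 0
  z <- (O - E) / denom
  z[untestable] <- NA_real_
  p <- 2 * pnorm(-abs(z))
  m <- sum(!untestable)
  sig <- !is.na(p) & p < alpha / m
  list(residuals = z, p = p, significant = sig, untestable = untestable, m = m)
}

#' Simulate group sentiment tables under the generator's emission law
#'
#' Under the synthetic generator, each sentence emits one sentiment-slot
#' category from the group's mix, so the corpus-level category counts per
#' group are exactly multinomial. This helper draws replicate group x
#' category tables from that reduction — equivalent in law to running the
#' full text generator, at a fraction of the cost — for calibration and
#' power studies of the chi-square machinery.
#'
#' @param n_reps number of replicate tables.
#' @param mix_covid,mix_non 3-simplexes over positive/negative/neutral.
#' @param n_tokens emissions per group (scalar or length-2).
#' @param seed integer.
#' @return list of 2 x 3 count matrices.
#' @export
simulate_sentiment_tables <- function(n_reps, mix_covid, mix_non,
                                      n_tokens, seed = 1L) {
  check_simplex(mix_covid, "mix_covid"); check_simplex(mix_non, "mix_non")
  n_tokens <- rep(n_tokens, length.out = 2L)
  with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      m <- rbind(covid = as.integer(rmultinom(1, n_tokens[1], mix_covid)),
                 non_covid = as.integer(rmultinom(1, n_tokens[2], mix_non)))
      colnames(m) <- c("positive", "negative", "neutral")
      m
    })
  })
}

#' Tidy export of a group sentiment table
#'
#' @param gt a [group_table()] result.
#' @param posthoc include Bonferroni significance flags per cell.
#' @return data.table (dictionary, group, category, count, pct, sig_flag).
#' @export
sentiment_tidy <- function(gt, posthoc = TRUE) {
  rows <- list()
  for (dict in names(gt)) {
    e <- gt[[dict]]
    ph <- if (posthoc) posthoc_bonferroni(e) else NULL
    cn <- colnames(e$counts)
    for (g in rownames(e$counts)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        dictionary = dict, group = g, category = cn,
        count = as.integer(e$counts[g, ]), pct = as.numeric(e$pct[g, ]),
        sig_flag = if (is.null(ph)) NA else as.logical(ph$significant[g, cn]))
    }
  }
  data.table::rbindlist(rows)
}
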