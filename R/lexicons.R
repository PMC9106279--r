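#' @name lexicons
#' @title Sentiment and valence-shifter lexicons
#'
#' @description
#' Four lexicon schemas are supported, all read from 2-column UTF-8 TSV files
#' (token, label-or-score; `#` lines are comments):
#'
#' * `emotion` — token to one or more of the 10 categories
#'   anger, anticipation, disgust, fear, joy, sadness, surprise, trust,
#'   negative, positive (NRC-style; a token may appear on several lines,
#'   one per category).
#' * `valence` — token to a nonzero integer score in \[-5, +5\] (Afinn-style).
#' * `binary` — token to `positive`/`negative`, stored as +1/-1 (Bing-style);
#'   this lexicon supplies the polarized-word polarity used by the sentence
#'   polarity score.
#' * `shifter` — token to a valence-shifter role `negator`, `amplifier`
#'   or `deamplifier`.
#'
#' Small fixture lexicons ship under `inst/extdata/`; real NRC/Afinn/Bing
#' files in the same schema are drop-in replacements by path.
NULL

EMOTION_CATEGORIES <- c("anger", "anticipation", "disgust", "fear", "joy",
                        "sadness", "surprise", "trust", "negative", "positive")
SHIFTER_ROLES <- c("negator", "amplifier", "deamplifier")

read_lexicon_lines <- function(path) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0L) stop("lexicon file '", path, "' has no entries", call. = FALSE)
  parts <- strsplit(raw[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed lexicon line %d in '%s': expected 2 tab-separated fields",
                 keep[bad[1L]], path), call. = FALSE)
  }
  data.frame(line = keep,
             token = tolower(vapply(parts, `[[`, "", 1L)),
             value = trimws(vapply(parts, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Read a sentiment or valence-shifter lexicon
#'
#' @param path TSV file (token TAB label-or-score), UTF-8, `#` comments allowed.
#' @param schema one of `"emotion"`, `"valence"`, `"binary"`, `"shifter"`.
#' @return an object of class `notepol_lexicon` with elements `schema` and
#'   `entries`: for `emotion`, a named list of category character vectors;
#'   otherwise a named numeric/character vector keyed by lowercased token.
#'   Duplicate tokens keep the last entry (with a warning), except in the
#'   emotion schema where multiple categories per token are the convention.
#' @examples
#' bing <- read_lexicon(notepol_extdata("bing_fixture.tsv"), "binary")
#' bing$entries[["estable"]]
#' @export
read_lexicon <- function(path, schema = c("emotion", "valence", "binary", "shifter")) {
  schema <- match.arg(schema)
  df <- read_lexicon_lines(path)
  entries <- switch(schema,
    emotion = {
      bad <- which(!df$value %in% EMOTION_CATEGORIES)
      if (length(bad)) {
        stop(sprintf("unknown emotion label '%s' at line %d of '%s'",
                     df$value[bad[1L]], df$line[bad[1L]], path), call. = FALSE)
      }
      lapply(split(df$value, df$token), function(v) sort(unique(v)))
    },
    valence = {
      score <- suppressWarnings(as.integer(df$value))
      bad <- which(is.na(score) | score == 0L | score < -5L | score > 5L |
                     as.numeric(df$value) != score)
      if (length(bad)) {
        stop(sprintf("valence score '%s' at line %d of '%s' is not a nonzero integer in [-5, 5]",
                     df$value[bad[1L]], df$line[bad[1L]], path), call. = FALSE)
      }
      warn_dupes(df, path)
      stats::setNames(score, df$token)[!duplicated(df$token, fromLast = TRUE)]
    },
    binary = {
      bad <- which(!df$value %in% c("positive", "negative"))
      if (length(bad)) {
        stop(sprintf("binary label '%s' at line %d of '%s' must be positive/negative",
                     df$value[bad[1L]], df$line[bad[1L]], path), call. = FALSE)
      }
      warn_dupes(df, path)
      v <- ifelse(df$value == "positive", 1, -1)
      stats::setNames(v, df$token)[!duplicated(df$token, fromLast = TRUE)]
    },
    shifter = {
      bad <- which(!df$value %in% SHIFTER_ROLES)
      if (length(bad)) {
        stop(sprintf("unknown shifter role '%s' at line %d of '%s'",
                     df$value[bad[1L]], df$line[bad[1L]], path), call. = FALSE)
      }
      warn_dupes(df, path)
      stats::setNames(df$value, df$token)[!duplicated(df$token, fromLast = TRUE)]
    })
  structure(list(schema = schema, entries = entries), class = "notepol_lexicon")
}

warn_dupes <- function(df, path) {
  dup <- unique(df$token[duplicated(df$token)])
  if (length(dup)) {
    warning(sprintf("duplicate token(s) in '%s' (last entry wins): %s",
                    path, paste(head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
}

#' Write a lexicon in canonical form
#'
#' Entries are sorted by token (and category for the emotion schema), one
#' `token<TAB>value` line each, so `write_lexicon(read_lexicon(f))` is a
#' canonicalizing round trip.
#'
#' @param lex a `notepol_lexicon`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "notepol_lexicon"))
  lines <- switch(lex$schema,
    emotion = {
      toks <- sort(names(lex$entries))
      unlist(lapply(toks, function(tk) paste(tk, lex$entries[[tk]], sep = "\t")))
    },
    valence = ,
    binary = {
      e <- lex$entries[sort(names(lex$entries))]
      val <- if (lex$schema == "binary") ifelse(e > 0, "positive", "negative") else as.integer(e)
      paste(names(e), val, sep = "\t")
    },
    shifter = {
      e <- lex$entries[sort(names(lex$entries))]
      paste(names(e), e, sep = "\t")
    })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Path to a packaged fixture data file
#'
#' @param file file name under the package's `extdata/` directory.
#' @return absolute path.
#' @export
notepol_extdata <- function(file) {
  p <- system.file("extdata", file, package = "notepol")
  if (p == "") stop("no packaged extdata file '", file, "'", call. = FALSE)
  p
}

#' Load the packaged fixture lexicon set
#'
#' Convenience loader for the four fixture lexicons that ship with the
#' package (synthetic sentiment tokens plus a handful of Spanish clinical
#' words). Warns if any binary-lexicon token collides with a shifter token.
#'
#' @return list with elements `emotion`, `valence`, `binary`, `shifter`.
#' @export
fixture_lexicons <- function() {
  lex <- list(
    emotion = read_lexicon(notepol_extdata("nrc_fixture.tsv"), "emotion"),
    valence = read_lexicon(notepol_extdata("afinn_fixture.tsv"), "valence"),
    binary  = read_lexicon(notepol_extdata("bing_fixture.tsv"), "binary"),
    shifter = read_lexicon(notepol_extdata("shifters_fixture.tsv"), "shifter")
  )
  overlap <- intersect(names(lex$binary$entries), names(lex$shifter$entries))
  if (length(overlap)) {
    warning("tokens present in both binary and shifter lexicons: ",
            paste(overlap, collapse = ", "), call. = FALSE)
  }
  lex
}
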