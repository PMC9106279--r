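#' Read a note file
#'
#' Expects a delimited UTF-8 file (CSV or TSV, autodetected) with header
#' columns `note_id, patient_id, group, shift, date, text`. Dates must be
#' ISO-8601; `group` must be `covid`/`non_covid`; `shift` must be
#' `morning`/`afternoon`/`night`.
#'
#' @param path file path.
#' @return data.table of notes with `date` parsed to `Date`.
#' @export
read_notes <- function(path) {
  notes <- data.table::fread(path, colClasses = list(character = "text"),
                             encoding = "UTF-8")
  need <- c("note_id", "patient_id", "group", "shift", "date", "text")
  miss <- setdiff(need, names(notes))
  if (length(miss)) stop("note file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  notes[, note_id := as.character(note_id)]
  notes[, patient_id := as.character(patient_id)]
  if (anyDuplicated(notes$note_id)) stop("note_id values are not unique", call. = FALSE)
  if (!all(notes$group %in% GROUPS)) stop("unknown group label", call. = FALSE)
  if (!all(notes$shift %in% SHIFTS)) stop("unknown shift label", call. = FALSE)
  d <- as.Date(as.character(notes$date), format = "%Y-%m-%d")
  if (anyNA(d)) stop("unparseable ISO-8601 date in note file", call. = FALSE)
  notes[, date := d]
  notes[]
}

#' Remove copy-paste duplicate notes
#'
#' A note is dropped when its whitespace-normalized, case-folded text is
#' identical to that of an earlier note in scope; the earliest record (by
#' date, then shift order morning < afternoon < night, then note id)
#' survives. Scope defaults to per patient — copy-paste happens within one
#' chart — but a corpus-wide scope is available.
#'
#' @param notes data.table of notes.
#' @param scope `"patient"` (default) or `"corpus"`.
#' @return list `kept` (data.table, original relative order), `removed`
#'   (count), `removed_ids` (character).
#' @export
deduplicate <- function(notes, scope = c("patient", "corpus")) {
  scope <- match.arg(scope)
  if (nrow(notes) == 0L) stop("empty note set", call. = FALSE)
  norm <- tolower(gsub("\\s+", " ", trimws(notes$text)))
  key <- if (scope == "patient") paste0(notes$patient_id, "\r", norm) else norm
  ord <- order(notes$date, match(notes$shift, SHIFTS), notes$note_id)
  dup_in_time_order <- duplicated(key[ord])
  removed_ids <- notes$note_id[ord][dup_in_time_order]
  keep <- !(notes$note_id %in% removed_ids)
  list(kept = notes[keep], removed = sum(!keep), removed_ids = removed_ids)
}

#' Tokenize a note and split it into sentences
#'
#' Sentences are split on `.`, `!`, `?` or newline. Tokens are maximal runs
#' of letters/digits (Unicode-aware, accents preserved) plus standalone
#' comma tokens — commas are retained because the polarity context-cluster
#' rule truncates at them. Everything is lowercased.
#'
#' @param text character scalar (one note's raw text).
#' @return list of character vectors, one per non-empty sentence. An empty
#'   or whitespace-only text yields an empty list (with a message).
#' @export
tokenize_and_split <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) {
    message("empty note text: produced 0 sentences")
    return(list())
  }
  pieces <- strsplit(tolower(text), "[.!?\n]+")[[1]]
  out <- lapply(pieces, function(s) {
    m <- gregexpr("[\\p{L}\\p{N}]+|,", s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(character(0))
    substring(s, m, m + attr(m, "match.length") - 1L)
  })
  out[lengths(out) > 0L]
}

#' Tokenize a whole corpus
#'
#' @param notes data.table of notes.
#' @return list of `notepol_tokenized_note` objects (fields `note_id`,
#'   `sentences`, `lemmas`, `content_lemmas`), in corpus order. `lemmas`
#'   and `content_lemmas` start equal to `sentences` until [lemmatize()] /
#'   [remove_stopwords()] are applied.
#' @export
tokenize_corpus <- function(notes) {
  lapply(seq_len(nrow(notes)), function(i) {
    s <- suppressMessages(tokenize_and_split(notes$text[i]))
    structure(list(note_id = notes$note_id[i], sentences = s,
                   lemmas = s, content_lemmas = s),
              class = "notepol_tokenized_note")
  })
}

#' Read a surface-to-lemma table
#'
#' TSV with two columns `surface<TAB>lemma`; `#` comment lines ignored.
#'
#' @param path file path.
#' @return named character vector (surface -> lemma, lowercased).
#' @export
read_lemma_table <- function(path) {
  df <- read_lexicon_lines(path)
  stats::setNames(tolower(df$value), df$token)
}

#' Lemmatize a tokenized note by table lookup
#'
#' Surfaces absent from the table map to themselves, so the operation is
#' idempotent whenever the table's lemmas are themselves fixed points.
#'
#' @param tok a `notepol_tokenized_note`.
#' @param lemma_table named character vector from [read_lemma_table()].
#' @return the note with `lemmas` (and `content_lemmas`) filled.
#' @export
lemmatize <- function(tok, lemma_table) {
  stopifnot(inherits(tok, "notepol_tokenized_note"))
  tok$lemmas <- lapply(tok$sentences, function(s) {
    hit <- lemma_table[s]
    unname(ifelse(is.na(hit), s, hit))
  })
  tok$content_lemmas <- tok$lemmas
  tok
}

#' Remove stopwords from a tokenized note's content lemmas
#'
#' Only `content_lemmas` is filtered: sentiment and topic stages consume
#' content lemmas, while the polarity stage deliberately keeps the full
#' sentences because negators and amplifiers are function words a stopword
#' list would delete.
#'
#' @param tok a `notepol_tokenized_note` (after [lemmatize()], or not).
#' @param stopwords character vector.
#' @return the note with `content_lemmas` filtered (comma tokens are also
#'   dropped — they are punctuation, not content).
#' @export
remove_stopwords <- function(tok, stopwords) {
  stopifnot(inherits(tok, "notepol_tokenized_note"))
  tok$content_lemmas <- lapply(tok$lemmas, function(s)
    s[!(s %in% stopwords) & s != ","])
  tok
}

#' Read a stopword list (one token per line)
#' @param path file path.
#' @return lowercased character vector.
#' @export
read_stopwords <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

#' Full preprocessing convenience wrapper
#'
#' [tokenize_corpus()] then [lemmatize()] then [remove_stopwords()].
#'
#' @param notes data.table of notes (already deduplicated if desired).
#' @param lemma_table named character vector (may be empty).
#' @param stopwords character vector (may be empty).
#' @return list of tokenized notes.
#' @export
preprocess_corpus <- function(notes, lemma_table = character(0),
                              stopwords = character(0)) {
  toks <- tokenize_corpus(notes)
  lapply(toks, function(tk) remove_stopwords(lemmatize(tk, lemma_table),
                                             stopwords))
}
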