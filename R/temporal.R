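#' Monthly sentiment / polarity series per group
#'
#' For sentiment categories the monthly value is the category's share of
#' the group's matched tokens that month; for polarity it is the monthly
#' mean of note polarity. Months with no notes for a group are omitted, so
#' series may have different lengths — that is what DTW is for. Groups with
#' fewer than two populated months are excluded with a warning.
#'
#' @param notes data.table of notes (for group and date lookup by note id).
#' @param profiles optional list of sentiment profiles (note order must
#'   match `notes`).
#' @param note_deltas optional data.table (note_id, delta) of note polarity.
#' @param dictionaries sentiment dictionaries to expand into categories.
#' @return list of `notepol_group_series` (fields `group`, `dictionary`,
#'   `category`, `months`, `values`).
#' @export
monthly_series <- function(notes, profiles = NULL, note_deltas = NULL,
                           dictionaries = c("nrc", "afinn", "bing")) {
  mons <- month_label(notes$date)
  out <- list()
  add <- function(group, dict, category, months, values) {
    if (length(values) < 2L) {
      warning(sprintf("series %s/%s/%s has < 2 populated months; excluded",
                      group, dict, category), call. = FALSE)
      return(invisible(NULL))
    }
    out[[length(out) + 1L]] <<- structure(
      list(group = group, dictionary = dict, category = category,
           months = months, values = values), class = "notepol_group_series")
  }
  for (g in unique(notes$group)) {
    idx <- which(notes$group == g)
    if (!is.null(profiles)) {
      for (dict in dictionaries) {
        counts <- profile_counts(profiles[idx], dict)
        bym <- rowsum(counts, mons[idx])
        tot <- rowSums(bym)
        keep <- tot > 0
        for (cat_ in colnames(bym)) {
          add(g, dict, cat_, rownames(bym)[keep], unname(bym[keep, cat_] / tot[keep]))
        }
      }
    }
    if (!is.null(note_deltas)) {
      dl <- note_deltas[match(notes$note_id[idx], note_id), ]
      ok <- !is.na(dl$delta)
      mg <- mons[idx][ok]
      agg <- tapply(dl$delta[ok], mg, mean)
      add(g, "polarity", "polarity", names(agg), as.numeric(agg))
    }
  }
  out
}

#' Dynamic time warping distance between two series
#'
#' Classic DTW dynamic program with squared-difference local cost and the
#' symmetric step pattern (match / insert / delete, unit weights). The
#' returned distance is \eqn{\sqrt{C^*} / (|a| + |b|)} — the accumulated
#' cost turned into a path-length-normalized Euclidean-type distance, which
#' is comparable across series of different lengths.
#'
#' @param a,b numeric vectors (length >= 2, finite) or
#'   `notepol_group_series` objects.
#' @return nonnegative scalar; 0 for identical series; symmetric in its
#'   arguments.
#' @export
dtw_distance <- function(a, b) {
  if (inherits(a, "notepol_group_series")) a <- a$values
  if (inherits(b, "notepol_group_series")) b <- b$values
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite values in series", call. = FALSE)
  }
  n <- length(a); m <- length(b)
  cost <- outer(a, b, function(x, y) (x - y)^2)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- cost[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  sqrt(D[n + 1L, m + 1L]) / (n + m)
}

#' Pairwise DTW distance matrix for a list of series
#'
#' @param series list of `notepol_group_series` or numeric vectors.
#' @param labels row/column names (defaults to `group/dictionary/category`).
#' @return symmetric matrix with zero diagonal.
#' @export
dtw_matrix <- function(series, labels = NULL) {
  if (is.null(labels)) {
    labels <- vapply(series, function(s) {
      if (inherits(s, "notepol_group_series"))
        paste(s$group, s$dictionary, s$category, sep = "/")
      else ""
    }, "")
    if (any(labels == "")) labels <- paste0("s", seq_along(series))
  }
  k <- length(series)
  M <- matrix(0, k, k, dimnames = list(labels, labels))
  if (k >= 2L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <- dtw_distance(series[[i]], series[[j]])
    }
  }
  M
}
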