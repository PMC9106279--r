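# Independent brute-force oracle for the sentence polarity score.
#
# Deliberately straight-line, index-by-index code, written before and kept
# independent of the production scorer in polarity.R. Tests assert exact
# agreement between the two on an exhaustive fixture grid, so any slip in
# either implementation of the cluster rule shows up as a mismatch.

oracle_delta <- function(tokens, binary_lexicon, shifter_lexicon,
                         before = 4L, after = 2L, c_weight = 0.8,
                         deamp_floor = -1, comma_truncation = TRUE) {
  stopifnot(inherits(binary_lexicon, "notepol_lexicon"),
            binary_lexicon$schema == "binary",
            inherits(shifter_lexicon, "notepol_lexicon"),
            shifter_lexicon$schema == "shifter")
  pol <- binary_lexicon$entries
  rol <- shifter_lexicon$entries

  n_words <- 0L
  for (t in tokens) if (t != ",") n_words <- n_words + 1L
  if (n_words == 0L) return(0)

  total <- 0
  for (i in seq_along(tokens)) {
    tk <- tokens[i]
    if (tk == "," || is.na(match(tk, names(pol)))) next
    p <- unname(pol[[tk]])

    # left window: up to `before` token positions, truncated after the
    # last comma inside the window when comma truncation is on
    lo <- i - before
    if (lo < 1L) lo <- 1L
    left <- if (i > 1L) seq(lo, i - 1L) else integer(0)
    if (comma_truncation && length(left) > 0L) {
      last_comma <- 0L
      for (j in left) if (tokens[j] == ",") last_comma <- j
      if (last_comma > 0L) {
        left <- left[left > last_comma]
      }
    }

    hi <- i + after
    if (hi > length(tokens)) hi <- length(tokens)
    right <- if (hi > i) seq(i + 1L, hi) else integer(0)

    n_neg <- 0L; n_amp <- 0L; n_deamp <- 0L
    for (j in c(left, right)) {
      cj <- tokens[j]
      if (cj == ",") next
      ridx <- match(cj, names(rol))
      if (is.na(ridx)) next
      role <- rol[[ridx]]
      if (role == "negator") n_neg <- n_neg + 1L
      else if (role == "amplifier") n_amp <- n_amp + 1L
      else if (role == "deamplifier") n_deamp <- n_deamp + 1L
    }

    amp_total <- c_weight * (n_amp - n_deamp)
    if (amp_total < deamp_floor) amp_total <- deamp_floor
    w <- p * (-1)^n_neg * (1 + amp_total)
    total <- total + w
  }
  total / sqrt(n_words)
}
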