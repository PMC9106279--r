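#' Derive a named RNG substream seed
#'
#' Every stochastic stage derives its own seed from the global seed plus a
#' stage name, so no stage consumes another stage's RNG stream and the run
#' manifest can record each seed. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param name character stream name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 1000000007
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% 2147483593L + 1L
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Validate that `p` is a probability simplex (nonneg, sums to 1).
check_simplex <- function(p, what = "probability vector", tol = 1e-8) {
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(sprintf("%s must be a simplex (nonnegative, summing to 1); got sum %.6f",
                 what, sum(p)), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Month index (1 = first month of the corpus' year span) from Date.
month_index <- function(dates) {
  d <- as.POSIXlt(dates)
  (d$year - min(d$year)) * 12L + d$mon + 1L
}

month_label <- function(dates) format(as.Date(dates), "%Y-%m")

SHIFTS <- c("morning", "afternoon", "night")
GROUPS <- c("covid", "non_covid")
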