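# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent sub-seeds from a master seed
#'
#' Expands one integer seed into a named set of sub-seeds so that the
#' different sources of randomness (basis sampling, covariates, treatment
#' assignment, outcome noise, splits, ...) use independent streams: changing
#' the sample size does not change the sampled basis, and vice versa.
#'
#' @param seed integer master seed.
#' @param names character vector naming the streams.
#' @return named integer vector of sub-seeds, each in [1, 2^31 - 2].
#' @keywords internal
derive_seeds <- function(seed, names) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  stats::setNames(s, names)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run an expression under a local RNG seed, leaving the caller's RNG
# stream untouched.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

# Squash a vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# Extract the covariate matrix (columns x1..xd) from a causal data frame.
covariate_matrix <- function(data) {
  xcols <- grep("^x[0-9]+$", names(data), value = TRUE)
  if (length(xcols) == 0L)
    stop("no covariate columns named x1, x2, ... found", call. = FALSE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  as.matrix(data[, xcols, drop = FALSE])
}
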