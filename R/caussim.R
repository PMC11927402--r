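# Ground-truth simulator for causal model-selection experiments.
#
# Response surfaces and the treatment-assignment logit are random expansions
# over Gaussian radial basis functions (RBF): smooth, bounded nonlinear
# functions whose complexity is controlled by the number of knots and the
# kernel bandwidth. A single scalar knob (overlap_strength) scales the
# propensity logit, moving the design continuously from a randomized trial
# (e = 1/2 everywhere) to strongly confounded, weak-overlap regimes.

#' Simulation configuration
#'
#' Bundles the parameters of the RBF potential-outcome generator.
#'
#' @param n_samples number of observations to draw.
#' @param dim covariate dimension; covariates are drawn uniformly on the
#'   unit hypercube \eqn{[0,1]^d} by default (bounded support keeps the
#'   Gaussian kernels informative everywhere), or from a random two-component
#'   Gaussian mixture when \code{covariate_law = "gauss_mix"}.
#' @param n_knots number of RBF knots of the generating basis.
#' @param bandwidth Gaussian kernel width (same units as the covariates).
#' @param overlap_strength nonnegative scale of the standardized propensity
#'   logit: 0 gives a randomized trial (propensity 1/2 everywhere); large
#'   values push propensities toward 0/1 (weak overlap). The logit is
#'   clamped to \eqn{\pm 8} so the propensity stays strictly inside (0, 1).
#' @param effect_scale scale of the treated-minus-control contrast: the
#'   treated coefficients are \code{w1 = w0 + effect_scale * delta} with
#'   \code{delta} standard normal, so this is the ratio of causal-effect
#'   variation to baseline variation.
#' @param noise_sd standard deviation of additive Gaussian outcome noise.
#' @param seed integer master seed; expanded into independent sub-streams
#'   for basis, covariates, assignment and noise, so changing
#'   \code{n_samples} does not change the sampled basis.
#' @param covariate_law \code{"uniform"} (default) or \code{"gauss_mix"}.
#' @param share_propensity_basis if \code{TRUE} the propensity logit uses
#'   the same knots as the outcome surfaces (confounding through the same
#'   nonlinearities); by default it gets independently sampled knots.
#' @return an object of class \code{"caussim_config"} (a named list).
#' @seealso [sample_caussim()], [sample_basis()]
#' @export
caussim_config <- function(n_samples = 1000L, dim = 2L, n_knots = 3L,
                           bandwidth = 0.4, overlap_strength = 0.5,
                           effect_scale = 1, noise_sd = 0.05, seed = 1L,
                           covariate_law = c("uniform", "gauss_mix"),
                           share_propensity_basis = FALSE) {
  covariate_law <- match.arg(covariate_law)
  assert_scalar_number(n_samples, "n_samples", lo = 1)
  assert_scalar_number(dim, "dim", lo = 1)
  assert_scalar_number(n_knots, "n_knots", lo = 1)
  assert_scalar_number(bandwidth, "bandwidth", lo = .Machine$double.eps)
  assert_scalar_number(overlap_strength, "overlap_strength", lo = 0)
  assert_scalar_number(effect_scale, "effect_scale")
  assert_scalar_number(noise_sd, "noise_sd", lo = 0)
  assert_scalar_number(seed, "seed")
  cfg <- list(n_samples = as.integer(n_samples), dim = as.integer(dim),
              n_knots = as.integer(n_knots), bandwidth = bandwidth,
              overlap_strength = overlap_strength,
              effect_scale = effect_scale, noise_sd = noise_sd,
              seed = as.integer(seed), covariate_law = covariate_law,
              share_propensity_basis = isTRUE(share_propensity_basis))
  class(cfg) <- "caussim_config"
  cfg
}

#' @export
print.caussim_config <- function(x, ...) {
  cat("RBF potential-outcome simulator configuration\n")
  cat(sprintf("  n = %d, dim = %d, knots = %d, bandwidth = %.3g\n",
              x$n_samples, x$dim, x$n_knots, x$bandwidth))
  cat(sprintf("  overlap_strength = %.3g, effect_scale = %.3g, noise_sd = %.3g\n",
              x$overlap_strength, x$effect_scale, x$noise_sd))
  cat(sprintf("  covariates: %s, seed = %d\n", x$covariate_law, x$seed))
  invisible(x)
}

# Draw n covariate rows from the configured law. The Gaussian-mixture law
# draws two component means inside the hypercube from the basis stream so
# that the mixture is a fixed feature of the data-generating process.
sample_covariates <- function(n, config, seed, mixture = NULL) {
  with_seed(seed, {
    if (config$covariate_law == "uniform") {
      matrix(stats::runif(n * config$dim), nrow = n, ncol = config$dim)
    } else {
      z <- sample.int(2L, n, replace = TRUE)
      mu <- mixture$means
      mu[z, , drop = FALSE] +
        matrix(stats::rnorm(n * config$dim, sd = mixture$sd), n, config$dim)
    }
  })
}

#' Sample a random RBF basis (the data-generating process)
#'
#' Draws the knots and coefficient vectors defining one data-generating
#' process: control surface \eqn{\mu_0 = \Phi w_0}, treated surface
#' \eqn{\mu_1 = \Phi w_1} with \eqn{w_1 = w_0 + \mathrm{effect\_scale}\,
#' \delta}, and a propensity logit built on its own (or shared) knots. The
#' logit is standardized against a fixed reference sample of the covariate
#' law stored with the basis, so that the propensity is a deterministic
#' function of x whose spread is exactly \code{overlap_strength}.
#'
#' @param config a [caussim_config()].
#' @param seed optional seed overriding the basis sub-stream of
#'   \code{config$seed}.
#' @return an object of class \code{"caussim_basis"}: knots (outcome and
#'   propensity), bandwidth, coefficient vectors \code{w0}, \code{w1},
#'   \code{w_e}, and the logit standardization constants.
#' @export
sample_basis <- function(config, seed = NULL) {
  stopifnot(inherits(config, "caussim_config"))
  seeds <- derive_seeds(config$seed, c("basis", "x", "a", "noise"))
  seed <- seed %||% seeds[["basis"]]
  k <- config$n_knots
  d <- config$dim
  basis <- with_seed(seed, {
    mixture <- list(means = matrix(stats::runif(2 * d), 2, d), sd = 0.2)
    knots <- matrix(stats::runif(k * d), nrow = k, ncol = d)
    w0 <- stats::rnorm(k)
    delta <- stats::rnorm(k)
    w1 <- w0 + config$effect_scale * delta
    knots_e <- if (config$share_propensity_basis) knots
               else matrix(stats::runif(k * d), nrow = k, ncol = d)
    w_e <- stats::rnorm(k)
    list(knots = knots, knots_e = knots_e, bandwidth = config$bandwidth,
         w0 = w0, w1 = w1, w_e = w_e, mixture = mixture)
  })
  # Standardize the raw propensity logit on a reference sample of the
  # covariate law (drawn from the basis stream, independent of n_samples).
  xref <- sample_covariates(4000L, config, seed + 1L, basis$mixture)
  u <- drop(rbf_features(xref, basis$knots_e, basis$bandwidth) %*% basis$w_e)
  basis$logit_center <- mean(u)
  basis$logit_scale <- max(stats::sd(u), 1e-12)
  class(basis) <- "caussim_basis"
  basis
}

#' Gaussian radial-basis-function features
#'
#' Entry (i, j) is \eqn{\exp(-\|x_i - \mathrm{knot}_j\|^2 / (2 b^2))};
#' values lie in (0, 1], equal to 1 exactly at a knot and decreasing
#' monotonically with distance.
#'
#' @param X numeric matrix (n x d) or vector (treated as one column).
#' @param knots numeric matrix (k x d) of kernel centers.
#' @param bandwidth positive kernel width b.
#' @return n x k feature matrix.
#' @export
rbf_features <- function(X, knots, bandwidth) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(knots)) knots <- matrix(knots, ncol = ncol(X))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("'bandwidth' must be a positive scalar", call. = FALSE)
  if (ncol(X) != ncol(knots))
    stop("covariates and knots must have the same dimension", call. = FALSE)
  # squared distances via the expansion |x - c|^2 = |x|^2 + |c|^2 - 2 x.c
  d2 <- outer(rowSums(X^2), rowSums(knots^2), "+") - 2 * X %*% t(knots)
  exp(-pmax(d2, 0) / (2 * bandwidth^2))
}

#' Evaluate the oracle surfaces of a basis
#'
#' Returns the true response surfaces and propensity at the given points:
#' \eqn{\mu_0 = \Phi w_0}, \eqn{\mu_1 = \Phi w_1}, and
#' \eqn{e = \mathrm{sigmoid}(s\,z(x))} where z is the standardized
#' propensity logit and s the overlap strength. The logit is clamped to
#' \eqn{\pm 8}, so e is bounded away from 0 and 1 (strong overlap holds by
#' construction, though it can be made arbitrarily weak).
#'
#' @param basis a [sample_basis()] result.
#' @param X covariate matrix.
#' @param overlap_strength nonnegative logit scale (0 = randomized trial).
#' @return list with vectors \code{mu0}, \code{mu1}, \code{e}.
#' @export
oracle_surfaces <- function(basis, X, overlap_strength = 1) {
  stopifnot(inherits(basis, "caussim_basis"))
  assert_scalar_number(overlap_strength, "overlap_strength", lo = 0)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  phi <- rbf_features(X, basis$knots, basis$bandwidth)
  mu0 <- drop(phi %*% basis$w0)
  mu1 <- drop(phi %*% basis$w1)
  phie <- rbf_features(X, basis$knots_e, basis$bandwidth)
  z <- (drop(phie %*% basis$w_e) - basis$logit_center) / basis$logit_scale
  logit <- clamp(overlap_strength * z, -8, 8)
  list(mu0 = mu0, mu1 = mu1, e = stats::plogis(logit))
}

#' Draw a simulated causal dataset
#'
#' Samples covariates from the configured law, assigns treatment
#' \eqn{a_i \sim \mathrm{Bernoulli}(e(x_i))} and generates the outcome
#' \eqn{y_i = \mu_{a_i}(x_i) + \varepsilon_i},
#' \eqn{\varepsilon_i \sim N(0, \mathrm{noise\_sd}^2)}. The returned data
#' frame carries the observed triplet together with every oracle column
#' needed for evaluation.
#'
#' @param config a [caussim_config()].
#' @param basis optional pre-sampled [sample_basis()]; one is drawn from the
#'   config seed when omitted.
#' @return a data frame of class \code{"causal_data"} with columns
#'   \code{x1..xd}, \code{a}, \code{y} and oracle columns \code{mu0},
#'   \code{mu1}, \code{e}, \code{m}, \code{tau}, where
#'   \code{m = e*mu1 + (1-e)*mu0} and \code{tau = mu1 - mu0}. The config
#'   and basis are attached as attributes.
#' @export
sample_caussim <- function(config, basis = NULL) {
  stopifnot(inherits(config, "caussim_config"))
  seeds <- derive_seeds(config$seed, c("basis", "x", "a", "noise"))
  if (is.null(basis)) basis <- sample_basis(config)
  n <- config$n_samples
  X <- sample_covariates(n, config, seeds[["x"]], basis$mixture)
  surf <- oracle_surfaces(basis, X, config$overlap_strength)
  a <- with_seed(seeds[["a"]], stats::rbinom(n, 1L, surf$e))
  eps <- if (config$noise_sd > 0)
    with_seed(seeds[["noise"]], stats::rnorm(n, sd = config$noise_sd))
  else rep(0, n)
  y <- ifelse(a == 1L, surf$mu1, surf$mu0) + eps
  out <- data.frame(X, a = a, y = y, mu0 = surf$mu0, mu1 = surf$mu1,
                    e = surf$e, m = surf$e * surf$mu1 + (1 - surf$e) * surf$mu0,
                    tau = surf$mu1 - surf$mu0)
  names(out)[seq_len(config$dim)] <- paste0("x", seq_len(config$dim))
  rownames(out) <- as.character(seq_len(n))
  attr(out, "config") <- config
  attr(out, "basis") <- basis
  class(out) <- c("causal_data", "data.frame")
  out
}

#' One-dimensional illustrative dataset
#'
#' A hand-built 1-D scenario in the spirit of a severity score (think of a
#' comorbidity index): the baseline risk \eqn{\mu_0} increases with x, the
#' treatment is beneficial (negative effect on the adverse outcome) for
#' sick patients (high x) and nearly null for healthy ones (low x), and
#' sicker patients are far more likely to be treated, creating a
#' poor-overlap region at high x.
#'
#' @param n number of observations (at least 2).
#' @param seed integer seed.
#' @param noise_sd outcome noise standard deviation.
#' @return a \code{"causal_data"} data frame (see [sample_caussim()]).
#' @export
make_toy_1d <- function(n, seed = 1L, noise_sd = 0.05) {
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  seeds <- derive_seeds(seed, c("x", "a", "noise"))
  x <- with_seed(seeds[["x"]], stats::runif(n))
  mu0 <- stats::plogis(6 * (x - 0.5))
  tau <- -0.8 * stats::plogis((x - 0.65) / 0.07)
  mu1 <- mu0 + tau
  e <- clamp(stats::plogis(5 * (x - 0.55)), 0.03, 0.97)
  a <- with_seed(seeds[["a"]], stats::rbinom(n, 1L, e))
  eps <- if (noise_sd > 0)
    with_seed(seeds[["noise"]], stats::rnorm(n, sd = noise_sd)) else rep(0, n)
  y <- ifelse(a == 1L, mu1, mu0) + eps
  out <- data.frame(x1 = x, a = a, y = y, mu0 = mu0, mu1 = mu1, e = e,
                    m = e * mu1 + (1 - e) * mu0, tau = tau)
  rownames(out) <- as.character(seq_len(n))
  attr(out, "config") <- list(type = "toy_1d", n_samples = n, dim = 1L,
                              noise_sd = noise_sd, seed = seed)
  class(out) <- c("causal_data", "data.frame")
  out
}

#' @export
print.causal_data <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Simulated causal dataset: %d rows, %d covariate(s), %.1f%% treated\n",
              nrow(x), sum(grepl("^x[0-9]+$", names(x))), 100 * mean(x$a)))
  if (!is.null(cfg$overlap_strength))
    cat(sprintf("  overlap_strength = %.3g, effect_scale = %.3g, noise_sd = %.3g\n",
                cfg$overlap_strength, cfg$effect_scale, cfg$noise_sd))
  NextMethod()
}

#' Write / read a causal dataset as CSV plus a JSON sidecar
#'
#' The CSV holds the columns \code{x1..xd}, \code{a}, \code{y} and any
#' oracle columns; the generating configuration is stored next to it in
#' \code{<path>.json}.
#'
#' @param data a \code{"causal_data"} data frame.
#' @param path CSV file path.
#' @return \code{write_causal_data} returns \code{path} invisibly;
#'   \code{read_causal_data} returns the \code{"causal_data"} data frame.
#' @export
write_causal_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  cfg <- attr(data, "config")
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_causal_data
#' @export
read_causal_data <- function(path) {
  out <- utils::read.csv(path)
  rownames(out) <- as.character(seq_len(nrow(out)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(cfg$n_samples)) class(cfg) <- "caussim_config"
    attr(out, "config") <- cfg
  }
  class(out) <- c("causal_data", "data.frame")
  out
}

#' Configuration sampler for benchmark runs
#'
#' Returns a function \code{f(seed)} producing a fresh [caussim_config()]
#' with the overlap strength drawn log-uniformly from \code{overlap_range},
#' so a benchmark run spans randomized-trial-like to weakly overlapping
#' designs, mirroring simulation studies that draw a random overlap
#' parameter per dataset. The log-uniform law is the natural draw for a
#' scale parameter: it spreads the resulting NTV overlap divergence evenly
#' instead of piling datasets into the weak-overlap regime.
#'
#' @param overlap_range length-2 positive range for \code{overlap_strength}.
#' @param ... further arguments fixed and passed on to [caussim_config()].
#' @return a function of one integer argument returning a config.
#' @export
caussim_config_sampler <- function(overlap_range = c(0.1, 5), ...) {
  fixed <- list(...)
  stopifnot(length(overlap_range) == 2L, all(overlap_range > 0))
  function(seed) {
    s <- with_seed(seed, exp(stats::runif(1, log(overlap_range[1]),
                                          log(overlap_range[2]))))
    do.call(caussim_config,
            c(list(overlap_strength = s, seed = as.integer(seed)), fixed))
  }
}
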