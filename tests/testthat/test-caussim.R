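# Simulator: RBF features, oracle surfaces, dataset invariants.

test_that("rbf features match the Gaussian kernel formula", {
  knots <- matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE)
  bw <- 0.5
  # a point sitting exactly on a knot has feature 1
  phi <- rbf_features(matrix(c(0, 0), 1), knots, bw)
  expect_equal(phi[1, 1], 1)
  # distance bw * sqrt(2) gives exp(-1)
  x <- matrix(c(bw * sqrt(2), 0), 1)
  phi <- rbf_features(x, matrix(c(0, 0), 1), bw)
  expect_equal(phi[1, 1], exp(-1))
  # strictly decreasing in the distance to the knot
  d <- seq(0, 2, length.out = 20)
  phi <- rbf_features(cbind(d, 0), matrix(c(0, 0), 1), bw)
  expect_true(all(diff(phi[, 1]) < 0))
  expect_true(all(phi > 0 & phi <= 1))
  expect_error(rbf_features(cbind(d, 0), knots, -1), "bandwidth")
})

test_that("basis sampling is deterministic with correct shapes", {
  cfg <- caussim_config(n_knots = 3, dim = 2, seed = 4)
  b1 <- sample_basis(cfg)
  b2 <- sample_basis(cfg)
  expect_identical(b1, b2)
  expect_equal(dim(b1$knots), c(3L, 2L))
  expect_length(b1$w0, 3)
  expect_length(b1$w1, 3)
  expect_length(b1$w_e, 3)
})

test_that("basis coefficients follow the standard-normal sampling law", {
  cfg <- caussim_config(n_knots = 3, dim = 2, effect_scale = 1)
  w0 <- unlist(lapply(1:300, function(s)
    sample_basis(caussim_config(n_knots = 3, seed = s))$w0))
  n <- length(w0)
  # mean and variance within 3 standard errors of N(0, 1)
  expect_lt(abs(mean(w0)), 3 / sqrt(n))
  expect_lt(abs(var(w0) - 1), 3 * sqrt(2 / n))
})

test_that("oracle surfaces honor the null-effect and randomized regimes", {
  cfg <- caussim_config(n_knots = 4, seed = 2, effect_scale = 0)
  b <- sample_basis(cfg)
  X <- matrix(runif(200), ncol = 2)
  surf <- oracle_surfaces(b, X, overlap_strength = 0)
  # zero effect scale makes w1 = w0, tau identically 0
  expect_equal(surf$mu1, surf$mu0)
  # zero overlap strength gives the randomized-trial propensity
  expect_equal(surf$e, rep(0.5, nrow(X)))
})

test_that("dataset invariants hold: m/tau identities, interior e, consistency", {
  d <- small_caussim(n = 500, seed = 3)
  expect_equal(d$m, d$e * d$mu1 + (1 - d$e) * d$mu0)
  expect_equal(d$tau, d$mu1 - d$mu0)
  expect_true(all(d$e > 0 & d$e < 1))
  # noiseless data satisfy the consistency assumption exactly
  d0 <- sample_caussim(caussim_config(n_samples = 300, noise_sd = 0, seed = 8))
  expect_equal(d0$y, ifelse(d0$a == 1, d0$mu1, d0$mu0))
})

test_that("generation is reproducible and treated fraction matches a randomized trial", {
  cfg <- caussim_config(n_samples = 400, seed = 21)
  expect_identical(sample_caussim(cfg), sample_caussim(cfg))
  cfg0 <- caussim_config(n_samples = 10000, overlap_strength = 0, seed = 13)
  d <- sample_caussim(cfg0)
  # binomial(n, 1/2): observed fraction within 3 standard errors
  expect_lt(abs(mean(d$a) - 0.5), 3 * sqrt(0.25 / nrow(d)))
})

test_that("the basis does not depend on the number of samples drawn", {
  b1 <- attr(sample_caussim(caussim_config(n_samples = 50, seed = 9)), "basis")
  b2 <- attr(sample_caussim(caussim_config(n_samples = 500, seed = 9)), "basis")
  expect_identical(b1, b2)
})

test_that("Robinson residual behaves under oracle inputs", {
  d0 <- sample_caussim(caussim_config(n_samples = 2000, noise_sd = 0, seed = 5))
  eps <- robinson_residual(d0$y, d0$a, d0$e, d0$m, d0$tau)
  expect_equal(eps, rep(0, nrow(d0)))
  sdn <- 0.3
  dn <- sample_caussim(caussim_config(n_samples = 4000, noise_sd = sdn, seed = 5))
  epsn <- robinson_residual(dn$y, dn$a, dn$e, dn$m, dn$tau)
  expect_lt(abs(mean(epsn)), 4 * sdn / sqrt(nrow(dn)))
  expect_lt(abs(sd(epsn) - sdn), 0.15 * sdn)
})

test_that("overlap knob monotonically increases the NTV divergence", {
  cfg <- caussim_config(seed = 17)
  b <- sample_basis(cfg)
  X <- matrix(runif(8000), ncol = 2)
  ntv <- vapply(c(0, 0.5, 1, 2, 4), function(s) {
    e <- oracle_surfaces(b, X, s)$e
    ntv_overlap(e)
  }, 0)
  expect_true(all(diff(ntv) >= -1e-12))
  expect_equal(ntv[1], 0)
})

test_that("the 1-D illustration has the intended effect and overlap profile", {
  d <- make_toy_1d(3000, seed = 2)
  q <- quantile(d$x1, c(0.1, 0.9))
  # harmful baseline is reduced by treatment only for sick (high-x) patients
  expect_lt(d$tau[which.min(abs(d$x1 - q[2]))], -0.3)
  expect_lt(abs(d$tau[which.min(abs(d$x1 - q[1]))]), 0.05)
  # sicker patients are more often treated: e among high-x differs from prevalence
  high <- d$x1 > median(d$x1)
  expect_gt(mean(d$e[high]), mean(d$a) + 0.1)
  expect_equal(d$m, d$e * d$mu1 + (1 - d$e) * d$mu0)
})

test_that("datasets round-trip through CSV with a JSON config sidecar", {
  d <- small_caussim(n = 50, seed = 6)
  path <- file.path(tempdir(), "ds.csv")
  write_causal_data(d, path)
  d2 <- read_causal_data(path)
  expect_equal(as.data.frame(d)[, names(d2)], as.data.frame(d2),
               tolerance = 1e-12, ignore_attr = TRUE)
  cfg <- attr(d2, "config")
  expect_equal(cfg$n_samples, 50)
  expect_equal(cfg$seed, 6)
  unlink(c(path, paste0(path, ".json")))
})
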