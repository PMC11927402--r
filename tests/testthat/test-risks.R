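# Causal risks: hand-computed values, algebraic identities, the
# reweighted-tau-risk representation of the R-risk.

test_that("single-observation risks match hand computations", {
  # r_risk: ((2 - 1) - (1 - 0.25) * 1)^2 = 0.0625
  expect_equal(r_risk(y = 2, a = 1, tau_f = 1, e = 0.25, m = 1), 0.0625)
  # u_risk: ((2 - 1)/(1 - 0.25) - 1)^2 = 1/9
  expect_equal(u_risk(y = 2, a = 1, tau_f = 1, e = 0.25, m = 1), 1 / 9)
  # tau_risk_ipw: (2 * (1/0.5) - 1)^2 = 9
  expect_equal(tau_risk_ipw(y = 2, a = 1, tau_f = 1, e = 0.5), 9)
  # mu_risk_ipw: (1/0.25) * (2 - 1)^2 = 4
  expect_equal(mu_risk_ipw(y = 2, a = 1, f_pred = 1, e = 0.25), 4)
})

test_that("vector risks match hand sums and definitions", {
  expect_equal(tau_risk(c(1, 1), c(0, 2)), 1)
  expect_equal(mu_risk(c(1, 3), c(0, 0)), 5)
  expect_equal(tau_risk(c(0.3, -1), c(0.3, -1)), 0)
  expect_error(tau_risk(NULL, 1), "feasible")
  # constant propensity 1/2 doubles the factual MSE exactly
  set.seed(3)
  y <- rnorm(50); f <- rnorm(50); a <- rbinom(50, 1, 0.5)
  expect_equal(mu_risk_ipw(y, a, f, rep(0.5, 50)), 2 * mu_risk(y, f))
})

test_that("risks are invariant to permuting the evaluation rows", {
  set.seed(4)
  n <- 60
  y <- rnorm(n); a <- rbinom(n, 1, 0.5); tau_f <- rnorm(n)
  e <- runif(n, 0.2, 0.8); m <- rnorm(n); f <- rnorm(n)
  p <- sample(n)
  expect_equal(r_risk(y, a, tau_f, e, m), r_risk(y[p], a[p], tau_f[p], e[p], m[p]))
  expect_equal(u_risk(y, a, tau_f, e, m), u_risk(y[p], a[p], tau_f[p], e[p], m[p]))
  expect_equal(mu_risk_ipw(y, a, f, e), mu_risk_ipw(y[p], a[p], f[p], e[p]))
  expect_equal(tau_risk_ipw(y, a, tau_f, e), tau_risk_ipw(y[p], a[p], tau_f[p], e[p]))
})

test_that("IPW mu-risk converges to the counterfactual-balanced MSE", {
  # 1-D check against direct integration: x ~ U(0,1), mu0 = x, mu1 = 2x,
  # noiseless, f = 0 on both arms. The arm-balanced error is
  # int (mu1 - 0)^2 + (mu0 - 0)^2 dx = 4/3 + 1/3 = 5/3, whatever e(x) is.
  set.seed(21)
  n <- 200000
  x <- runif(n)
  e <- plogis(2 * (x - 0.5))
  a <- rbinom(n, 1, e)
  y <- ifelse(a == 1, 2 * x, x)
  est <- mu_risk_ipw(y, a, rep(0, n), e, eta = NULL)
  expect_lt(abs(est - 5 / 3), 0.05)
})

test_that("the pseudo-outcome is an unbiased ATE estimator under oracle e", {
  d <- sample_caussim(caussim_config(n_samples = 10000, seed = 19,
                                     overlap_strength = 1))
  pseudo <- d$y * (d$a / d$e - (1 - d$a) / (1 - d$e))
  ate <- mean(d$tau)
  se <- sd(pseudo) / sqrt(nrow(d))
  expect_lt(abs(mean(pseudo) - ate), 3 * se)
})

test_that("noiseless oracle inputs zero the R- and U-risks at the true CATE", {
  d <- sample_caussim(caussim_config(n_samples = 500, noise_sd = 0, seed = 23))
  expect_equal(r_risk(d$y, d$a, d$tau, d$e, d$m), 0)
  expect_equal(u_risk(d$y, d$a, d$tau, d$e, d$m, eta = NULL), 0)
})

test_that("U-risk variance inflates as propensities approach the boundary", {
  # two points with identical residuals, one with extreme e
  summand <- function(e) ((1 - 0.5) / (1 - e) - 0)^2
  expect_gt(summand(0.99), 100 * summand(0.5))
})

test_that("R-risk equals the overlap-weighted tau-risk (randomized, noiseless)", {
  d <- sample_caussim(caussim_config(n_samples = 800, noise_sd = 0,
                                     overlap_strength = 0, seed = 3))
  fits <- fit_family(tiny_family(), d)
  for (f in fits[c(1, 5, 9)]) {
    tau_f <- predict_cate(f, d)
    r <- r_risk(d$y, d$a, tau_f, d$e, d$m)
    # e = 1/2: (a - e)^2 = 1/4 exactly, so the identity is exact
    expect_equal(r, 0.25 * tau_risk(d$tau, tau_f))
    expect_equal(r, reweighted_tau_risk(d$tau, tau_f, d$e))
  }
})

test_that("R-risk tracks the reweighted tau-risk across random confounded configs", {
  # Monte-Carlo agreement at rate ~ 1/sqrt(n) on noiseless data
  for (seed in 1:20) {
    cfg <- caussim_config(n_samples = 2000, noise_sd = 0,
                          overlap_strength = runif(1, 0, 2) , seed = seed)
    d <- sample_caussim(cfg)
    tau_f <- d$tau * 0.7 + 0.2  # a deliberately imperfect candidate
    r <- r_risk(d$y, d$a, tau_f, d$e, d$m)
    rw <- reweighted_tau_risk(d$tau, tau_f, d$e)
    scale <- mean((d$tau - tau_f)^2)
    expect_lt(abs(r - rw), 5 / sqrt(nrow(d)) * max(scale, 0.01))
  }
})

test_that("Bayes residual terms equal the noise variance for homoscedastic noise", {
  e <- runif(100, 0.1, 0.9)
  bt <- bayes_residual_terms(0.3, e)
  expect_equal(bt$total, 0.09)
  expect_equal(bt$sigma2_b1 + bt$sigma2_b0, 0.09)
  # with noise, the reweighted tau-risk gains exactly the Bayes terms
  d <- sample_caussim(caussim_config(n_samples = 4000, noise_sd = 0.3, seed = 2))
  tau_f <- d$tau * 0.5
  r <- r_risk(d$y, d$a, tau_f, d$e, d$m)
  rw <- reweighted_tau_risk(d$tau, tau_f, d$e,
                            bayes_terms = bayes_residual_terms(0.3, d$e)$total)
  expect_lt(abs(r - rw) / rw, 0.1)
})

test_that("reweighted tau-risk differences are independent of the Bayes terms", {
  set.seed(6)
  tau <- rnorm(200); e <- runif(200, 0.2, 0.8)
  f1 <- tau + rnorm(200, sd = 0.3); f2 <- tau + rnorm(200, sd = 0.6)
  for (bt in c(0, 0.5)) {
    diffs <- reweighted_tau_risk(tau, f1, e, bt) -
      reweighted_tau_risk(tau, f2, e, bt)
    expect_equal(diffs, mean(e * (1 - e) * ((tau - f1)^2 - (tau - f2)^2)))
  }
})

test_that("compute_risk_table fills every cell and enforces leakage checks", {
  d <- small_caussim(n = 500, seed = 25)
  sp <- split_data(d, 0.8, seed = 1)
  fits <- fit_family(tiny_family(), sp$train)
  nuis <- fit_nuisances(sp$train, seed = 2)
  tab <- compute_risk_table(fits, sp$test, nuisances = nuis)
  expect_s3_class(tab, "risk_table")
  expect_equal(nrow(tab), length(fits))
  cols <- c("mu_risk", "tau_risk_oracle", "mu_risk_ipw_semi", "tau_risk_ipw_semi",
            "u_risk_semi", "r_risk_semi", "mu_risk_ipw_feas",
            "tau_risk_ipw_feas", "u_risk_feas", "r_risk_feas")
  expect_true(all(cols %in% names(tab)))
  num <- as.matrix(tab[, cols])
  expect_true(all(is.finite(num)))
  expect_true(all(num >= 0))
  # semi-oracle and feasible R-risks rank candidates consistently
  expect_gt(kendall_tau(tab$r_risk_semi, tab$r_risk_feas), 0)
  # scoring on training rows is refused
  expect_error(compute_risk_table(fits, sp$train, nuisances = nuis),
               "leakage")
  # without oracle columns only feasible risks appear
  d2 <- sp$test[, c("x1", "x2", "a", "y")]
  class(d2) <- class(sp$test)
  tab2 <- compute_risk_table(fits, d2, nuisances = nuis)
  expect_false("tau_risk_oracle" %in% names(tab2))
})

test_that("risk tables round-trip to CSV with JSON metadata", {
  d <- small_caussim(n = 300, seed = 33)
  sp <- split_data(d, 0.8, seed = 4)
  fits <- fit_family(tiny_family(), sp$train)
  tab <- compute_risk_table(fits, sp$test)
  path <- file.path(tempdir(), "risks.csv")
  write_risk_table(tab, path)
  back <- read.csv(path)
  expect_equal(back$candidate_id, tab$candidate_id)
  expect_equal(back$mu_risk, tab$mu_risk, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$eta, 1e-3)
  unlink(c(path, paste0(path, ".json")))
})
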