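# Candidate families, meta-learner fitting, induced CATE/ATE.

test_that("family builders produce the documented grids", {
  fam <- build_caussim_family()
  expect_length(fam, 120)
  ids <- vapply(fam, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0)
  expect_length(build_caussim_family(n_bases = 1), 12)
  # identifiers are stable across calls with the same seed
  expect_identical(ids, vapply(build_caussim_family(), `[[`, "", "id"))
  lambdas <- unique(vapply(fam, `[[`, 0, "lambda"))
  expect_setequal(lambdas, c(1e-3, 1e-2, 1e-1, 1, 1e1, 1e2))
  expect_setequal(unique(vapply(fam, `[[`, "", "learner_kind")),
                  c("TLearner", "SftLearner"))

  gbt <- build_gbt_family()
  expect_length(gbt, 18)
  expect_true(all(vapply(gbt, `[[`, "", "learner_kind") == "SLearner"))
  grid <- unique(data.frame(
    lr = vapply(gbt, `[[`, 0, "learning_rate"),
    leaves = vapply(gbt, `[[`, 0L, "max_leaf_nodes")))
  expect_equal(nrow(grid), 18)
  expect_setequal(unique(grid$lr), c(0.01, 0.1, 1))
  expect_setequal(unique(grid$leaves), c(25L, 27L, 30L, 32L, 35L, 40L))
})

test_that("TLearner with identical arms induces a null CATE", {
  set.seed(1)
  X <- matrix(runif(400), ncol = 2)
  y <- sin(3 * X[, 1]) + X[, 2]
  # duplicate every row into both arms with identical outcomes
  d <- data.frame(x1 = rep(X[, 1], 2), x2 = rep(X[, 2], 2),
                  a = rep(0:1, each = 200), y = rep(y, 2))
  rownames(d) <- as.character(seq_len(nrow(d)))
  spec <- candidate_spec("TLearner", "ridge_rbf", featurization_seed = 3,
                         lambda = 1e-3)
  fit <- fit_candidate(spec, d)
  tau_f <- predict_cate(fit, X)
  expect_lt(max(abs(tau_f)), 0.1)
})

test_that("very strong ridge regularization shrinks predictions to arm means", {
  d <- small_caussim(n = 600, seed = 4)
  spec <- candidate_spec("TLearner", "ridge_rbf", featurization_seed = 2,
                         lambda = 1e9)
  fit <- fit_candidate(spec, d)
  X <- as.matrix(d[, c("x1", "x2")])
  for (arm in 0:1) {
    pred <- predict(fit, X, arm)
    expect_lt(max(abs(pred - mean(d$y[d$a == arm]))), 0.01)
  }
})

test_that("SLearner differs between arms only through the treatment feature", {
  d <- small_caussim(n = 500, seed = 7)
  spec <- candidate_spec("SLearner", "ridge_rbf", featurization_seed = 1,
                         lambda = 1)
  fit <- fit_candidate(spec, d)
  X <- as.matrix(d[, c("x1", "x2")])
  # single linear model on (features, a): arm contrast is a constant shift
  tau_f <- predict_cate(fit, X)
  expect_lt(diff(range(tau_f)), 1e-10)
})

test_that("predict_cate equals the arm-contrast of predict", {
  d <- small_caussim(n = 500, seed = 9)
  spec <- candidate_spec("SftLearner", "ridge_rbf", featurization_seed = 5,
                         lambda = 0.1)
  fit <- fit_candidate(spec, d)
  X <- as.matrix(d[1:50, c("x1", "x2")])
  expect_equal(predict_cate(fit, X),
               predict(fit, X, 1) - predict(fit, X, 0))
})

test_that("estimate_ate is the mean CATE and is permutation invariant", {
  d <- small_caussim(n = 400, seed = 2)
  fit <- fit_candidate(tiny_family()[[1]], d)
  X <- as.matrix(d[, c("x1", "x2")])
  expect_equal(estimate_ate(fit, X), mean(predict_cate(fit, X)))
  perm <- sample(nrow(X))
  expect_equal(estimate_ate(fit, X[perm, ]), estimate_ate(fit, X))
  expect_error(estimate_ate(fit, X[0, , drop = FALSE]), "at least one row")
})

test_that("fitting errors name an empty treatment arm", {
  d <- small_caussim(n = 200, seed = 3)
  d$a <- 0L
  spec <- candidate_spec("TLearner", "ridge_rbf")
  expect_error(fit_candidate(spec, d), "arm a = 1")
})

test_that("a well-specified candidate recovers the true surfaces as regularization vanishes", {
  cfg <- caussim_config(n_samples = 5000, noise_sd = 0, n_knots = 2, seed = 31)
  d <- sample_caussim(cfg)
  basis <- attr(d, "basis")
  # hand the candidate the generating featurization: with vanishing ridge
  # penalty and no noise, each arm's regression interpolates its surface
  spec <- candidate_spec("SftLearner", "ridge_rbf", lambda = 1e-10)
  fit <- fit_candidate(spec, d)
  fit$fit$arms <- lapply(0:1, function(arm) {
    feat <- list(knots = basis$knots, bandwidth = basis$bandwidth)
    Phi <- rbf_features(as.matrix(d[d$a == arm, c("x1", "x2")]),
                        feat$knots, feat$bandwidth)
    list(feat = feat,
         ridge = cateselect:::fit_ridge(Phi, d$y[d$a == arm], 1e-10))
  })
  tau_f <- predict_cate(fit, as.matrix(d[, c("x1", "x2")]))
  scale <- mean(d$tau^2) + 1
  expect_lt(tau_risk(d$tau, tau_f) / scale, 1e-8)
})

test_that("the boosting SLearner fits and induces a nonzero CATE", {
  d <- small_caussim(n = 500, seed = 12)
  fit <- fit_candidate(build_gbt_family()[[5]], d)
  tau_f <- predict_cate(fit, d)
  expect_length(tau_f, nrow(d))
  expect_true(all(is.finite(tau_f)))
})
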