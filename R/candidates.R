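# Candidate outcome-model families and their fitting routines.
#
# A candidate is a regression model f(x, a) of the outcome; contrasting its
# two arms induces CATE and ATE estimates (g-computation). Two built-in
# families are provided:
#   * ridge regressions on random 2-knot Gaussian-kernel featurizations,
#     combined as TLearner or SftLearner meta-learners (120 members with
#     the default grid), and
#   * an SLearner grid of gradient-boosted trees (18 members).

RIDGE_LAMBDA_GRID <- c(1e-3, 1e-2, 1e-1, 1, 1e1, 1e2)
GBT_LEARNING_RATES <- c(0.01, 0.1, 1)
GBT_MAX_LEAVES <- c(25L, 27L, 30L, 32L, 35L, 40L)

#' Candidate model specification
#'
#' @param learner_kind one of \code{"SLearner"}, \code{"SftLearner"},
#'   \code{"TLearner"}: a single model of (x, a); two regressors on one
#'   shared random featurization; or fully separate featurizations and
#'   regressors per arm.
#' @param base_model \code{"ridge_rbf"} (ridge on 2-knot Gaussian-kernel
#'   features) or \code{"gbt"} (gradient-boosted trees).
#' @param featurization_seed integer selecting the random knots
#'   (ridge_rbf only).
#' @param lambda ridge penalty (ridge_rbf only).
#' @param learning_rate,max_leaf_nodes boosting hyperparameters (gbt only).
#' @param id identifier string; a stable one is built when omitted.
#' @return an object of class \code{"candidate_spec"}.
#' @export
candidate_spec <- function(learner_kind = c("TLearner", "SftLearner", "SLearner"),
                           base_model = c("ridge_rbf", "gbt"),
                           featurization_seed = 1L, lambda = 1,
                           learning_rate = 0.1, max_leaf_nodes = 31L,
                           id = NULL) {
  learner_kind <- match.arg(learner_kind)
  base_model <- match.arg(base_model)
  if (base_model == "ridge_rbf")
    assert_scalar_number(lambda, "lambda", lo = .Machine$double.xmin)
  spec <- list(learner_kind = learner_kind, base_model = base_model,
               featurization_seed = as.integer(featurization_seed),
               lambda = lambda, learning_rate = learning_rate,
               max_leaf_nodes = as.integer(max_leaf_nodes))
  spec$id <- id %||% (if (base_model == "ridge_rbf")
    sprintf("%s_b%03d_lam%s", learner_kind, spec$featurization_seed %% 1000L,
            formatC(lambda, format = "e", digits = 0))
  else
    sprintf("%s_gbt_lr%s_leaf%02d", learner_kind,
            formatC(learning_rate, format = "g"), spec$max_leaf_nodes))
  class(spec) <- "candidate_spec"
  spec
}

#' Build the ridge-on-RBF candidate family
#'
#' Cross product of the six ridge penalties \eqn{\lambda \in \{10^{-3},
#' \dots, 10^{2}\}}, the TLearner and SftLearner meta-learners, and
#' \code{n_bases} random featurization seeds: 120 candidates with the
#' defaults.
#'
#' @param n_bases number of random featurizations (default 10).
#' @param seed seed from which the featurization seeds are derived.
#' @return list of [candidate_spec()] objects with unique identifiers.
#' @export
build_caussim_family <- function(n_bases = 10L, seed = 0L) {
  if (n_bases < 1) stop("'n_bases' must be at least 1", call. = FALSE)
  feat_seeds <- derive_seeds(seed, paste0("feat", seq_len(n_bases)))
  grid <- expand.grid(b = seq_len(n_bases),
                      kind = c("TLearner", "SftLearner"),
                      lambda = RIDGE_LAMBDA_GRID, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    candidate_spec(grid$kind[i], "ridge_rbf",
                   featurization_seed = feat_seeds[[grid$b[i]]],
                   lambda = grid$lambda[i],
                   id = sprintf("%s_b%02d_lam%s", grid$kind[i], grid$b[i],
                                formatC(grid$lambda[i], format = "e",
                                        digits = 0)))
  })
  stopifnot(!anyDuplicated(vapply(specs, `[[`, "", "id")))
  specs
}

#' Build the gradient-boosting SLearner family
#'
#' SLearner gradient-boosted trees over the grid learning rate
#' \{0.01, 0.1, 1\} x maximum leaf nodes \{25, 27, 30, 32, 35, 40\}:
#' 18 candidates.
#'
#' @return list of [candidate_spec()] objects.
#' @export
build_gbt_family <- function() {
  grid <- expand.grid(lr = GBT_LEARNING_RATES, leaves = GBT_MAX_LEAVES)
  lapply(seq_len(nrow(grid)), function(i)
    candidate_spec("SLearner", "gbt", learning_rate = grid$lr[i],
                   max_leaf_nodes = grid$leaves[i]))
}

# ---- ridge on standardized features, unpenalized intercept ----------------

fit_ridge <- function(Phi, y, lambda) {
  center <- colMeans(Phi)
  scale <- apply(Phi, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  Z <- sweep(sweep(Phi, 2L, center), 2L, scale, "/")
  yc <- y - mean(y)
  k <- ncol(Z)
  beta <- solve(crossprod(Z) + diag(lambda, k), crossprod(Z, yc))
  list(center = center, scale = scale, beta = drop(beta), intercept = mean(y))
}

predict_ridge <- function(fit, Phi) {
  Z <- sweep(sweep(Phi, 2L, fit$center), 2L, fit$scale, "/")
  drop(Z %*% fit$beta) + fit$intercept
}

# Random 2-knot Gaussian-kernel featurization; the bandwidth is the median
# pairwise distance of (a subsample of) the rows used, fixed per seed.
make_featurization <- function(X, seed, n_knots = 2L) {
  with_seed(seed, {
    idx <- sample.int(nrow(X), min(n_knots, nrow(X)))
    knots <- X[idx, , drop = FALSE]
    sub <- X[sample.int(nrow(X), min(200L, nrow(X))), , drop = FALSE]
    bw <- stats::median(stats::dist(sub))
    list(knots = knots, bandwidth = max(bw, 1e-6))
  })
}

featurize <- function(feat, X) rbf_features(X, feat$knots, feat$bandwidth)

# ---- fitting --------------------------------------------------------------

#' Fit a candidate outcome model
#'
#' @param spec a [candidate_spec()].
#' @param train a causal data frame (columns \code{x1..xd}, \code{a},
#'   \code{y}); TLearner and SftLearner require both treatment arms to be
#'   present.
#' @return an object of class \code{"fitted_candidate"} exposing
#'   \code{predict(fit, X, a)}, [predict_cate()] and [estimate_ate()]. The
#'   row names of the training data are recorded as a fingerprint used by
#'   [compute_risk_table()] to detect train/evaluation leakage.
#' @export
fit_candidate <- function(spec, train) {
  stopifnot(inherits(spec, "candidate_spec"))
  X <- covariate_matrix(train)
  a <- train$a
  y <- train$y
  if (spec$learner_kind %in% c("TLearner", "SftLearner")) {
    for (arm in 0:1)
      if (sum(a == arm) < 1L)
        stop(sprintf("cannot fit %s: treatment arm a = %d is empty",
                     spec$learner_kind, arm), call. = FALSE)
  }
  fit <- switch(
    paste(spec$base_model, spec$learner_kind, sep = "."),
    "ridge_rbf.TLearner" = {
      # separate featurizations: knots are drawn from each arm's own rows
      # (the same sub-seed keeps symmetric arms exactly symmetric)
      arms <- lapply(0:1, function(arm) {
        Xa <- X[a == arm, , drop = FALSE]
        feat <- make_featurization(Xa, spec$featurization_seed)
        list(feat = feat,
             ridge = fit_ridge(featurize(feat, Xa), y[a == arm], spec$lambda))
      })
      list(arms = arms)
    },
    "ridge_rbf.SftLearner" = {
      feat <- make_featurization(X, spec$featurization_seed)
      Phi <- featurize(feat, X)
      arms <- lapply(0:1, function(arm)
        list(feat = feat,
             ridge = fit_ridge(Phi[a == arm, , drop = FALSE], y[a == arm],
                               spec$lambda)))
      list(arms = arms)
    },
    "ridge_rbf.SLearner" = {
      feat <- make_featurization(X, spec$featurization_seed)
      Phi <- cbind(featurize(feat, X), a = a)
      list(feat = feat, ridge = fit_ridge(Phi, y, spec$lambda))
    },
    "gbt.SLearner" = {
      dtrain <- xgboost::xgb.DMatrix(cbind(X, a = a), label = y)
      params <- list(objective = "reg:squarederror",
                     eta = spec$learning_rate,
                     max_leaves = spec$max_leaf_nodes,
                     grow_policy = "lossguide", tree_method = "hist",
                     max_depth = 0L, nthread = 1L)
      list(booster = xgboost::xgb.train(params = params, data = dtrain,
                                        nrounds = 100L, verbose = 0L))
    },
    stop(sprintf("unsupported candidate: %s with %s", spec$learner_kind,
                 spec$base_model), call. = FALSE)
  )
  structure(list(spec = spec, fit = fit, dim = ncol(X),
                 train_rows = rownames(train)),
            class = "fitted_candidate")
}

# Arm-wise response-surface prediction mu_a(x).
predict_arm <- function(object, X, arm) {
  spec <- object$spec
  fit <- object$fit
  if (!is.matrix(X)) X <- covariate_matrix(X)
  if (spec$learner_kind %in% c("TLearner", "SftLearner")) {
    armfit <- fit$arms[[arm + 1L]]
    predict_ridge(armfit$ridge, featurize(armfit$feat, X))
  } else if (spec$base_model == "ridge_rbf") {
    Phi <- cbind(featurize(fit$feat, X), a = rep(arm, nrow(X)))
    predict_ridge(fit$ridge, Phi)
  } else {
    m <- cbind(X, a = rep(as.numeric(arm), nrow(X)))
    stats::predict(fit$booster, xgboost::xgb.DMatrix(m))
  }
}

#' Predict from a fitted candidate
#'
#' @param object a \code{"fitted_candidate"}.
#' @param X covariate matrix or causal data frame.
#' @param a treatment arm: a scalar (0/1) or a vector of length
#'   \code{nrow(X)}.
#' @param ... unused.
#' @return numeric vector of outcome predictions f(x, a).
#' @export
predict.fitted_candidate <- function(object, X, a, ...) {
  if (!is.matrix(X)) X <- covariate_matrix(X)
  if (length(a) == 1L) return(predict_arm(object, X, a))
  stopifnot(length(a) == nrow(X))
  out <- numeric(nrow(X))
  for (arm in 0:1) {
    sel <- a == arm
    if (any(sel)) out[sel] <- predict_arm(object, X[sel, , drop = FALSE], arm)
  }
  out
}

#' @export
print.fitted_candidate <- function(x, ...) {
  cat(sprintf("Fitted candidate '%s' (%s, %s), trained on %d rows\n",
              x$spec$id, x$spec$learner_kind, x$spec$base_model,
              length(x$train_rows)))
  invisible(x)
}

#' CATE induced by a fitted candidate
#'
#' Elementwise contrast of the two predicted response surfaces,
#' \eqn{\hat\tau_f(x) = \hat\mu_1(x) - \hat\mu_0(x)}.
#'
#' @param fit a \code{"fitted_candidate"}.
#' @param X covariate matrix or causal data frame.
#' @return numeric vector of CATE predictions.
#' @export
predict_cate <- function(fit, X) {
  if (!is.matrix(X)) X <- covariate_matrix(X)
  predict_arm(fit, X, 1L) - predict_arm(fit, X, 0L)
}

#' ATE induced by a fitted candidate (g-computation plug-in)
#'
#' Sample mean of the predicted CATE over the given points.
#'
#' @inheritParams predict_cate
#' @return scalar ATE estimate.
#' @export
estimate_ate <- function(fit, X) {
  if (!is.matrix(X)) X <- covariate_matrix(X)
  if (nrow(X) == 0L) stop("'X' must contain at least one row", call. = FALSE)
  mean(predict_cate(fit, X))
}

#' Fit every candidate of a family
#'
#' @param family list of [candidate_spec()]s.
#' @param train causal data frame.
#' @return named list of \code{"fitted_candidate"} objects keyed by id.
#' @export
fit_family <- function(family, train) {
  fits <- lapply(family, fit_candidate, train = train)
  names(fits) <- vapply(fits, function(f) f$spec$id, "")
  fits
}
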