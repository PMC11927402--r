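# Nuisance estimation: propensity e(x) = P(A = 1 | X = x) and conditional
# mean outcome m(x) = E[Y | X = x].
#
# Each nuisance is a stacked estimator with two members -- a penalized
# linear model and gradient-boosted trees -- combined by a convex weight
# learned on out-of-fold predictions. Hyperparameters are set by nested
# cross-validation (inner folds for the hyperparameter search, outer folds
# for the stacking weight), then both members are refit on the full
# training set. The propensity member and stack are scored with the Brier
# score, which is minimized by the true conditional probability; the mean
# outcome with mean squared error.

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; minimized in expectation by the true conditional probability.
#'
#' @param p probability vector in [0, 1].
#' @param a binary vector of the same length.
#' @return scalar mean of \eqn{(p_i - a_i)^2}.
#' @export
brier_score <- function(p, a) {
  if (length(p) != length(a))
    stop("'p' and 'a' must have the same length", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  mean((p - a)^2)
}

#' Clip propensities away from 0 and 1
#'
#' Guards the divisions in inverse-propensity-weighted risks.
#'
#' @param e propensity vector in [0, 1].
#' @param eta clipping level in (0, 0.5); values are forced into
#'   [eta, 1 - eta].
#' @return clipped vector.
#' @export
bound_propensity <- function(e, eta = 1e-3) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 0.5)
    stop("'eta' must be a scalar in (0, 0.5)", call. = FALSE)
  if (any(e < 0 | e > 1)) stop("'e' must lie in [0, 1]", call. = FALSE)
  clamp(e, eta, 1 - eta)
}

# fold assignment, optionally stratified on a binary label
make_folds <- function(n, k, seed, strata = NULL) {
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(strata)) strata <- rep(1L, n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# add a quadratic column for one-dimensional inputs (glmnet needs >= 2
# columns; the expansion also gives the linear member minimal curvature)
augment_linear <- function(X) if (ncol(X) >= 2L) X else cbind(X, X^2)

NUISANCE_LAMBDA_GRID <- 10^seq(2, -4, length.out = 7)
NUISANCE_GBT_GRID <- expand.grid(eta = c(0.1, 0.3), max_depth = c(2L, 3L))

# ---- members --------------------------------------------------------------

fit_linear_member <- function(X, y, family, fold_inner) {
  if (family == "gaussian" && stats::sd(y) < 1e-10)
    return(list(kind = "const", value = mean(y), cv_score = 0))
  Xa <- augment_linear(X)
  grid <- NUISANCE_LAMBDA_GRID
  cv <- matrix(NA_real_, length(grid), max(fold_inner))
  for (f in seq_len(max(fold_inner))) {
    tr <- fold_inner != f
    fit <- glmnet::glmnet(Xa[tr, , drop = FALSE], y[tr], family = family,
                          alpha = 0, lambda = grid)
    p <- stats::predict(fit, Xa[!tr, , drop = FALSE], s = grid,
                        type = "response")
    cv[, f] <- colMeans((p - y[!tr])^2)
  }
  score <- rowMeans(cv)
  lambda <- grid[which.min(score)]
  model <- glmnet::glmnet(Xa, y, family = family, alpha = 0, lambda = grid)
  list(kind = "linear", model = model, lambda = lambda, family = family,
       cv_score = min(score))
}

fit_gbt_member <- function(X, y, objective, fold_inner, nrounds = 60L) {
  grid <- NUISANCE_GBT_GRID
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(max(fold_inner))
    for (f in seq_len(max(fold_inner))) {
      tr <- fold_inner != f
      bst <- xgb_fit(X[tr, , drop = FALSE], y[tr], objective,
                     grid$eta[g], grid$max_depth[g], nrounds)
      p <- stats::predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
      errs[f] <- mean((p - y[!tr])^2)
    }
    score[g] <- mean(errs)
  }
  best <- which.min(score)
  model <- xgb_fit(X, y, objective, grid$eta[best], grid$max_depth[best],
                   nrounds)
  list(kind = "gbt", model = model, eta = grid$eta[best],
       max_depth = grid$max_depth[best], objective = objective,
       nrounds = nrounds, cv_score = min(score))
}

xgb_fit <- function(X, y, objective, eta, max_depth, nrounds) {
  params <- list(objective = objective, eta = eta, max_depth = max_depth,
                 tree_method = "hist", nthread = 1L)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(X, label = y),
                     nrounds = nrounds, verbose = 0L)
}

predict_member <- function(member, X) {
  if (member$kind == "const") {
    rep(member$value, nrow(X))
  } else if (member$kind == "linear") {
    drop(stats::predict(member$model, augment_linear(X), s = member$lambda,
                        type = "response"))
  } else {
    stats::predict(member$model, xgboost::xgb.DMatrix(X))
  }
}

refit_member <- function(member, X, y) {
  if (member$kind == "const") {
    member$value <- mean(y)
  } else if (member$kind == "linear") {
    Xa <- augment_linear(X)
    member$model <- glmnet::glmnet(Xa, y, family = member$family, alpha = 0,
                                   lambda = NUISANCE_LAMBDA_GRID)
  } else {
    member$model <- xgb_fit(X, y, member$objective, member$eta,
                            member$max_depth, member$nrounds)
  }
  member
}

# ---- stack ----------------------------------------------------------------

# Fit one stacked nuisance: hyperparameters by inner CV on the full
# training data, stacking weight from outer-fold out-of-fold predictions,
# members refit on all rows.
fit_stack <- function(X, y, task = c("propensity", "outcome"),
                      outer_folds, inner_folds, seed) {
  task <- match.arg(task)
  n <- nrow(X)
  strata <- if (task == "propensity") y else NULL
  fold_outer <- make_folds(n, outer_folds, seed, strata)
  fold_inner <- make_folds(n, inner_folds, seed + 1L, strata)
  family <- if (task == "propensity") "binomial" else "gaussian"
  objective <- if (task == "propensity") "binary:logistic"
               else "reg:squarederror"

  lin <- fit_linear_member(X, y, family, fold_inner)
  gbt <- fit_gbt_member(X, y, objective, fold_inner)

  oof <- matrix(NA_real_, n, 2L)
  for (f in seq_len(outer_folds)) {
    tr <- fold_outer != f
    lin_f <- refit_member(lin, X[tr, , drop = FALSE], y[tr])
    gbt_f <- refit_member(gbt, X[tr, , drop = FALSE], y[tr])
    oof[!tr, 1L] <- predict_member(lin_f, X[!tr, , drop = FALSE])
    oof[!tr, 2L] <- predict_member(gbt_f, X[!tr, , drop = FALSE])
  }
  d <- oof[, 1L] - oof[, 2L]
  denom <- sum(d^2)
  w <- if (denom < 1e-12) 0.5 else clamp(sum(d * (y - oof[, 2L])) / denom, 0, 1)
  stacked_oof <- w * oof[, 1L] + (1 - w) * oof[, 2L]
  if (task == "propensity") stacked_oof <- clamp(stacked_oof, 0, 1)

  list(task = task, members = list(linear = lin, gbt = gbt), weight = w,
       cv_score = mean((stacked_oof - y)^2),
       member_cv_scores = c(linear = lin$cv_score, gbt = gbt$cv_score),
       fold_outer = fold_outer, fold_inner = fold_inner)
}

predict_stack <- function(stack, X) {
  p <- stack$weight * predict_member(stack$members$linear, X) +
    (1 - stack$weight) * predict_member(stack$members$gbt, X)
  if (stack$task == "propensity") clamp(p, 1e-6, 1 - 1e-6) else p
}

# ---- public surface -------------------------------------------------------

#' Fit nuisance estimators on a training set
#'
#' Fits the stacked propensity model \eqn{\check e(x)} on (x, a) and the
#' stacked conditional-mean-outcome model \eqn{\check m(x)} on (x, y)
#' (regressing on x only: m is the conditional mean over the factual
#' distribution, marginal over treatment).
#'
#' @param train causal data frame with both treatment arms present and
#'   finite outcomes.
#' @param outer_folds folds for the stacking weight (out-of-fold
#'   predictions); default 5.
#' @param inner_folds folds of the hyperparameter search; default 3.
#' @param seed integer seed for the fold assignments.
#' @param source provenance label, \code{"shared-train"} or
#'   \code{"separate-nuisance-set"}.
#' @return object of class \code{"nuisance_fit"} with elements
#'   \code{e_stack}, \code{m_stack} and \code{fit_report} (chosen
#'   hyperparameters, cross-validated Brier score / MSE, fold indices).
#'   Predict with [predict_e()] / [predict_m()]; predicted propensities are
#'   always strictly inside (0, 1).
#' @export
fit_nuisances <- function(train, outer_folds = 5L, inner_folds = 3L,
                          seed = 1L, source = "shared-train") {
  X <- covariate_matrix(train)
  a <- train$a
  y <- train$y
  if (length(unique(a)) < 2L)
    stop("both treatment arms must be present to fit the propensity model",
         call. = FALSE)
  if (any(!is.finite(y))) stop("'y' contains non-finite values", call. = FALSE)
  seeds <- derive_seeds(seed, c("e", "m"))
  e_stack <- fit_stack(X, a, "propensity", outer_folds, inner_folds,
                       seeds[["e"]])
  m_stack <- fit_stack(X, y, "outcome", outer_folds, inner_folds,
                       seeds[["m"]])
  report <- list(
    e = list(brier_cv = e_stack$cv_score,
             member_brier_cv = e_stack$member_cv_scores,
             weight_linear = e_stack$weight,
             lambda = e_stack$members$linear$lambda,
             gbt = list(eta = e_stack$members$gbt$eta,
                        max_depth = e_stack$members$gbt$max_depth),
             fold_outer = e_stack$fold_outer,
             fold_inner = e_stack$fold_inner),
    m = list(mse_cv = m_stack$cv_score,
             member_mse_cv = m_stack$member_cv_scores,
             weight_linear = m_stack$weight,
             lambda = m_stack$members$linear$lambda,
             gbt = list(eta = m_stack$members$gbt$eta,
                        max_depth = m_stack$members$gbt$max_depth),
             fold_outer = m_stack$fold_outer,
             fold_inner = m_stack$fold_inner))
  structure(list(e_stack = e_stack, m_stack = m_stack, fit_report = report,
                 source = source),
            class = "nuisance_fit")
}

#' Predict nuisances at new points
#'
#' @param nuisances a [fit_nuisances()] result.
#' @param X covariate matrix or causal data frame.
#' @return \code{predict_e}: propensities strictly in (0, 1);
#'   \code{predict_m}: conditional mean outcomes.
#' @export
predict_e <- function(nuisances, X) {
  stopifnot(inherits(nuisances, "nuisance_fit"))
  if (!is.matrix(X)) X <- covariate_matrix(X)
  predict_stack(nuisances$e_stack, X)
}

#' @rdname predict_e
#' @export
predict_m <- function(nuisances, X) {
  stopifnot(inherits(nuisances, "nuisance_fit"))
  if (!is.matrix(X)) X <- covariate_matrix(X)
  predict_stack(nuisances$m_stack, X)
}

#' @export
print.nuisance_fit <- function(x, ...) {
  cat(sprintf("Stacked nuisance estimators (%s)\n", x$source))
  cat(sprintf("  e(x): CV Brier = %.4f (linear weight %.2f)\n",
              x$fit_report$e$brier_cv, x$fit_report$e$weight_linear))
  cat(sprintf("  m(x): CV MSE   = %.4f (linear weight %.2f)\n",
              x$fit_report$m$mse_cv, x$fit_report$m$weight_linear))
  invisible(x)
}
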