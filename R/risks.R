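# Causal model-selection risks.
#
# All risks are finite-sum (plain sample mean) estimators. "Semi-oracle"
# means the true simulated nuisances (e, m) are plugged in; "feasible"
# means estimated nuisances. The oracle tau-risk (PEHE) needs the true
# CATE and exists only on simulated data.
#
# Risks that divide by e or 1 - e clip the propensity to [eta, 1 - eta]
# (default eta = 1e-3) before dividing; the R-risk involves no division
# and uses the propensity unclipped.

#' Oracle tau-risk (PEHE)
#'
#' Mean squared error between the true and the candidate CATE,
#' \eqn{\mathrm{mean}((\tau(x_i) - \hat\tau_f(x_i))^2)}. The oracle
#' selection criterion: feasible only on simulated data.
#'
#' @param tau_true true CATE vector (from the simulator).
#' @param tau_f candidate CATE predictions.
#' @return scalar risk.
#' @export
tau_risk <- function(tau_true, tau_f) {
  if (is.null(tau_true) || !length(tau_true))
    stop("the oracle CATE is unavailable; use a feasible risk (r_risk, ...)",
         call. = FALSE)
  stopifnot(length(tau_true) == length(tau_f))
  mean((tau_true - tau_f)^2)
}

#' Factual mu-risk (mean squared error)
#'
#' The standard regression MSE on observed outcomes,
#' \eqn{\mathrm{mean}((y_i - f(x_i; a_i))^2)}.
#'
#' @param y observed outcomes.
#' @param f_pred candidate predictions at the observed treatment.
#' @return scalar risk.
#' @export
mu_risk <- function(y, f_pred) {
  stopifnot(length(y) == length(f_pred))
  mean((y - f_pred)^2)
}

#' Inverse-propensity-weighted mu-risk
#'
#' Factual squared error reweighted by \eqn{a/e + (1-a)/(1-e)}, which
#' balances the treated and control contributions.
#'
#' @inheritParams mu_risk
#' @param a binary treatment vector.
#' @param e propensity vector, strictly inside (0, 1) after clipping.
#' @param eta clipping level passed to [bound_propensity()]; \code{NULL}
#'   disables clipping (an error is raised if e touches 0 or 1).
#' @return scalar risk.
#' @export
mu_risk_ipw <- function(y, a, f_pred, e, eta = 1e-3) {
  stopifnot(length(y) == length(a), length(y) == length(f_pred),
            length(y) == length(e))
  e <- prepare_propensity(e, eta)
  w <- a / e + (1 - a) / (1 - e)
  mean(w * (y - f_pred)^2)
}

#' Pseudo-outcome tau-risk (IPW form)
#'
#' Squared distance between the Horvitz-Thompson pseudo-outcome
#' \eqn{y (a/e - (1-a)/(1-e))}, whose conditional expectation is the CATE,
#' and the candidate CATE.
#'
#' @inheritParams mu_risk_ipw
#' @param tau_f candidate CATE predictions.
#' @return scalar risk.
#' @export
tau_risk_ipw <- function(y, a, tau_f, e, eta = 1e-3) {
  stopifnot(length(y) == length(a), length(y) == length(tau_f),
            length(y) == length(e))
  e <- prepare_propensity(e, eta)
  pseudo <- y * (a / e - (1 - a) / (1 - e))
  mean((pseudo - tau_f)^2)
}

#' U-risk
#'
#' Squared distance between the U-learner target
#' \eqn{(y - m(x)) / (a - e(x))} and the candidate CATE. Divides by
#' \eqn{a - e}, so its variance inflates when propensities approach 0 or 1.
#'
#' @inheritParams tau_risk_ipw
#' @param m conditional mean outcome at the evaluation points.
#' @return scalar risk.
#' @export
u_risk <- function(y, a, tau_f, e, m, eta = 1e-3) {
  stopifnot(length(y) == length(a), length(y) == length(tau_f),
            length(y) == length(e), length(y) == length(m))
  e <- prepare_propensity(e, eta)
  denom <- a - e
  if (any(abs(denom) < 1e-12))
    stop("|a - e| is numerically zero: overlap too weak for the U-risk",
         call. = FALSE)
  mean(((y - m) / denom - tau_f)^2)
}

#' R-risk
#'
#' Squared Robinson-decomposition residual of the candidate,
#' \eqn{\mathrm{mean}(((y_i - m_i) - (a_i - e_i)\hat\tau_f(x_i))^2)}.
#' Involves no division by the propensity.
#'
#' @inheritParams u_risk
#' @return scalar risk.
#' @export
r_risk <- function(y, a, tau_f, e, m) {
  stopifnot(length(y) == length(a), length(y) == length(tau_f),
            length(y) == length(e), length(y) == length(m))
  mean(((y - m) - (a - e) * tau_f)^2)
}

prepare_propensity <- function(e, eta) {
  if (is.null(eta)) {
    if (any(e <= 0 | e >= 1))
      stop("propensities touch 0/1; clip them (set 'eta') before weighting",
           call. = FALSE)
    return(e)
  }
  bound_propensity(e, eta)
}

#' Robinson-decomposition residual
#'
#' \eqn{\varepsilon_i = y_i - m_i - (a_i - e_i)\,\tau(x_i)}. With the
#' oracle nuisances and the true CATE this residual has conditional mean
#' zero, and is identically zero on noiseless data.
#'
#' @param y,a observed outcome and treatment.
#' @param e,m nuisances at the evaluation points.
#' @param tau a CATE vector (true or candidate).
#' @return residual vector.
#' @export
robinson_residual <- function(y, a, e, m, tau) {
  stopifnot(length(y) == length(a), length(y) == length(e),
            length(y) == length(m), length(y) == length(tau))
  y - m - (a - e) * tau
}

#' Overlap-reweighted tau-risk (population form of the R-risk)
#'
#' The R-risk equals the tau-risk reweighted by \eqn{e(x)(1 - e(x))} plus
#' candidate-independent propensity-weighted Bayes residual terms:
#' this computes \eqn{\mathrm{mean}(e_i (1-e_i) (\tau_i - \hat\tau_{f,i})^2)
#' + \tilde\sigma^2_B(1) + \tilde\sigma^2_B(0)}. With a deterministic
#' outcome link (no noise) the Bayes terms vanish.
#'
#' @param tau_true true CATE vector.
#' @param tau_f candidate CATE predictions.
#' @param e true propensity vector.
#' @param bayes_terms scalar \eqn{\tilde\sigma^2_B(1) + \tilde\sigma^2_B(0)};
#'   see [bayes_residual_terms()].
#' @return scalar risk.
#' @export
reweighted_tau_risk <- function(tau_true, tau_f, e, bayes_terms = 0) {
  stopifnot(length(tau_true) == length(tau_f), length(tau_true) == length(e))
  mean(e * (1 - e) * (tau_true - tau_f)^2) + bayes_terms
}

#' Propensity-weighted Bayes residual terms of the simulator
#'
#' With homoscedastic Gaussian outcome noise of standard deviation
#' \eqn{\sigma}, \eqn{\sigma^2_y(x; a) = \sigma^2} for both arms, so the
#' propensity-weighted Bayes errors are
#' \eqn{\tilde\sigma^2_B(1) = \sigma^2\,\mathrm{mean}(e)} and
#' \eqn{\tilde\sigma^2_B(0) = \sigma^2\,\mathrm{mean}(1 - e)}, summing to
#' \eqn{\sigma^2}.
#'
#' @param noise_sd outcome noise standard deviation.
#' @param e propensity vector (used only for the decomposition into arms).
#' @return list with \code{sigma2_b1}, \code{sigma2_b0} and their
#'   \code{total}.
#' @export
bayes_residual_terms <- function(noise_sd, e) {
  s2 <- noise_sd^2
  list(sigma2_b1 = s2 * mean(e), sigma2_b0 = s2 * mean(1 - e),
       total = s2)
}

# column order of the risk table
RISK_NAMES <- c("mu_risk", "mu_risk_ipw", "tau_risk_ipw", "u_risk", "r_risk")

#' Compute the full risk table for a set of candidates
#'
#' Scores every fitted candidate on an evaluation set with each risk:
#' the oracle tau-risk (when the evaluation data carry the true CATE),
#' the semi-oracle risks (true nuisances, suffix \code{_semi}) and the
#' feasible risks (estimated nuisances, suffix \code{_feas}). Candidates
#' must have been fitted on rows disjoint from the evaluation rows; the
#' training fingerprint recorded by [fit_candidate()] is checked.
#'
#' @param fits named list of \code{"fitted_candidate"} objects (or a list
#'   of [candidate_spec()]s together with \code{train}).
#' @param eval_set causal data frame to score on.
#' @param nuisances optional [fit_nuisances()] result for feasible risks.
#' @param use_oracle include oracle/semi-oracle columns when the evaluation
#'   data carry \code{mu0}, \code{mu1}, \code{e}, \code{m}, \code{tau}.
#' @param eta propensity clipping level for the dividing risks.
#' @param check_leakage verify train/evaluation disjointness.
#' @return data frame of class \code{"risk_table"}: one row per candidate
#'   (key column \code{candidate_id}), one column per risk; metadata
#'   (nuisance source, eta) in attributes.
#' @export
compute_risk_table <- function(fits, eval_set, nuisances = NULL,
                               use_oracle = TRUE, eta = 1e-3,
                               check_leakage = TRUE) {
  stopifnot(is.list(fits), length(fits) > 0L)
  X <- covariate_matrix(eval_set)
  a <- eval_set$a
  y <- eval_set$y
  eval_rows <- rownames(eval_set)
  has_oracle <- use_oracle && all(c("e", "m", "tau") %in% names(eval_set))

  if (check_leakage) {
    for (f in fits) {
      if (length(intersect(f$train_rows, eval_rows)))
        stop(sprintf("leakage: candidate '%s' was trained on evaluation rows",
                     f$spec$id), call. = FALSE)
    }
  }

  e_hat <- if (!is.null(nuisances)) predict_e(nuisances, X)
  m_hat <- if (!is.null(nuisances)) predict_m(nuisances, X)

  rows <- lapply(fits, function(f) {
    pred <- predict(f, X, a)
    tau_f <- predict_cate(f, X)
    out <- list(candidate_id = f$spec$id, mu_risk = mu_risk(y, pred))
    if (has_oracle) {
      out$tau_risk_oracle <- tau_risk(eval_set$tau, tau_f)
      out$mu_risk_ipw_semi <- mu_risk_ipw(y, a, pred, eval_set$e, eta)
      out$tau_risk_ipw_semi <- tau_risk_ipw(y, a, tau_f, eval_set$e, eta)
      out$u_risk_semi <- u_risk(y, a, tau_f, eval_set$e, eval_set$m, eta)
      out$r_risk_semi <- r_risk(y, a, tau_f, eval_set$e, eval_set$m)
    }
    if (!is.null(nuisances)) {
      out$mu_risk_ipw_feas <- mu_risk_ipw(y, a, pred, e_hat, eta)
      out$tau_risk_ipw_feas <- tau_risk_ipw(y, a, tau_f, e_hat, eta)
      out$u_risk_feas <- u_risk(y, a, tau_f, e_hat, m_hat, eta)
      out$r_risk_feas <- r_risk(y, a, tau_f, e_hat, m_hat)
    }
    as.data.frame(out)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "eta") <- eta
  attr(tab, "nuisance_source") <- if (!is.null(nuisances)) nuisances$source
  class(tab) <- c("risk_table", "data.frame")
  tab
}

#' Write a risk table to CSV with a JSON metadata sidecar
#'
#' @param tab a \code{"risk_table"}.
#' @param path CSV path; metadata goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_risk_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  meta <- list(eta = attr(tab, "eta"),
               nuisance_source = attr(tab, "nuisance_source"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
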