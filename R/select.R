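# Train/test model-selection procedure: split the data, fit candidates and
# nuisances on the train side, score every candidate with every risk on the
# test side, and select the risk minimizer.

#' Split a causal dataset into train and test sets
#'
#' The split is stratified by treatment arm (largest-remainder allocation),
#' which guarantees both arms are represented in the train set whenever the
#' data allow it.
#'
#' @param data causal data frame.
#' @param train_fraction fraction of rows in the train set, strictly in
#'   (0, 1); default 0.9.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list with \code{train}, \code{test} (data frames keeping their
#'   original row names) and the index vectors \code{train_idx},
#'   \code{test_idx}; a disjoint, exhaustive partition of the rows.
#' @export
split_data <- function(data, train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be strictly between 0 and 1", call. = FALSE)
  n <- nrow(data)
  n_train <- round(n * train_fraction)
  if (n_train < 1L || n_train >= n)
    stop("split leaves an empty train or test set", call. = FALSE)
  arms <- split(seq_len(n), data$a)
  # largest-remainder allocation of n_train across arms
  quota <- vapply(arms, length, 0L) * train_fraction
  base <- pmin(floor(quota), vapply(arms, length, 0L))
  left <- n_train - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    for (i in ord) {
      if (left == 0) break
      if (base[i] < length(arms[[i]])) { base[i] <- base[i] + 1L; left <- left - 1L }
    }
  }
  train_idx <- with_seed(seed, {
    sort(unlist(lapply(seq_along(arms), function(i)
      sample(arms[[i]], base[i])), use.names = FALSE))
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(unique(data$a[train_idx])) < 2L && length(unique(data$a)) == 2L)
    stop("could not place both treatment arms in the train set", call. = FALSE)
  list(train = data[train_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Select the risk-minimizing candidate from a risk table
#'
#' @param risk_table a [compute_risk_table()] result.
#' @param risk_name name of the risk column to minimize (e.g.
#'   \code{"r_risk_feas"}).
#' @return the selected \code{candidate_id}. Ties are broken by the
#'   lexicographically smallest identifier.
#' @export
select_best <- function(risk_table, risk_name) {
  if (!risk_name %in% names(risk_table))
    stop(sprintf("risk column '%s' not present in the risk table", risk_name),
         call. = FALSE)
  v <- risk_table[[risk_name]]
  if (any(!is.finite(v)))
    stop(sprintf("non-finite %s for candidate(s): %s", risk_name,
                 paste(risk_table$candidate_id[!is.finite(v)], collapse = ", ")),
         call. = FALSE)
  ids <- risk_table$candidate_id
  best <- which(v == min(v))
  sort(ids[best])[1L]
}

# map (risk, source) to a risk-table column
risk_column <- function(risk_name, risk_source) {
  if (risk_name == "tau_risk") return("tau_risk_oracle")
  if (risk_name == "mu_risk") return("mu_risk")
  suffix <- switch(risk_source, feasible = "_feas", semi_oracle = "_semi")
  paste0(risk_name, suffix)
}

#' Causal model selection by risk minimization on a held-out test set
#'
#' The main fitting function. Splits the data (stratified by arm), fits
#' every candidate of the family and the stacked nuisance estimators on the
#' train side, computes the full risk table on the test side and selects
#' the candidate minimizing the configured risk.
#'
#' @param data causal data frame (simulated data carry oracle columns and
#'   additionally yield oracle/semi-oracle diagnostics).
#' @param family list of [candidate_spec()]s; default
#'   [build_caussim_family()].
#' @param risk risk driving the selection: one of \code{"r_risk"},
#'   \code{"u_risk"}, \code{"tau_risk_ipw"}, \code{"mu_risk_ipw"},
#'   \code{"mu_risk"} or \code{"tau_risk"} (oracle, simulated data only).
#' @param risk_source \code{"feasible"} (estimated nuisances, default) or
#'   \code{"semi_oracle"} (true nuisances).
#' @param train_fraction fraction of rows used to fit candidates and
#'   nuisances; default 0.9 (the split that empirically yields the best
#'   selection).
#' @param nuisance_set \code{"shared"}: nuisances fit on the same train set
#'   as the candidates; \code{"separate"}: the train set is halved into a
#'   nuisance half and a candidate half.
#' @param seed integer seed controlling the split and nuisance folds.
#' @param outer_folds,inner_folds nuisance cross-validation folds, see
#'   [fit_nuisances()].
#' @param eta propensity clipping level used inside dividing risks.
#' @return object of class \code{"cate_select"}: the risk table, the
#'   selected candidate id and its fitted model, split indices, nuisances
#'   and oracle diagnostics when available. Methods: \code{print},
#'   \code{summary}, \code{predict} (CATE of the selected model),
#'   \code{coef} (its ATE), \code{plot}.
#' @examples
#' data <- sample_caussim(caussim_config(n_samples = 400, seed = 7))
#' sel <- select_cate(data, family = build_caussim_family(n_bases = 2),
#'                    risk = "r_risk", seed = 7)
#' print(sel)
#' head(predict(sel, data))
#' @export
select_cate <- function(data, family = build_caussim_family(),
                        risk = c("r_risk", "u_risk", "tau_risk_ipw",
                                 "mu_risk_ipw", "mu_risk", "tau_risk"),
                        risk_source = c("feasible", "semi_oracle"),
                        train_fraction = 0.9,
                        nuisance_set = c("shared", "separate"),
                        seed = 1L, outer_folds = 5L, inner_folds = 3L,
                        eta = 1e-3) {
  risk <- match.arg(risk)
  risk_source <- match.arg(risk_source)
  nuisance_set <- match.arg(nuisance_set)
  if (length(family) == 0L) stop("'family' is empty", call. = FALSE)
  has_oracle <- all(c("e", "m", "tau") %in% names(data))
  if (risk == "tau_risk" && !has_oracle)
    stop("the oracle tau-risk requires simulated data with oracle columns",
         call. = FALSE)
  seeds <- derive_seeds(seed, c("split", "nuisance", "subsplit"))

  sp <- split_data(data, train_fraction, seeds[["split"]])
  if (nuisance_set == "separate") {
    sub <- split_data(sp$train, 0.5, seeds[["subsplit"]])
    nuisance_train <- sub$train
    candidate_train <- sub$test
    source <- "separate-nuisance-set"
  } else {
    nuisance_train <- candidate_train <- sp$train
    source <- "shared-train"
  }

  fits <- fit_family(family, candidate_train)
  nuis <- fit_nuisances(nuisance_train, outer_folds, inner_folds,
                        seeds[["nuisance"]], source = source)
  tab <- compute_risk_table(fits, sp$test, nuisances = nuis,
                            use_oracle = has_oracle, eta = eta)
  column <- risk_column(risk, risk_source)
  selected <- select_best(tab, column)

  diagnostics <- NULL
  if (has_oracle) {
    diagnostics <- list(
      tau_risk_selected = tab$tau_risk_oracle[tab$candidate_id == selected],
      tau_risk_best = min(tab$tau_risk_oracle),
      excess_tau_risk = excess_tau_risk(tab, selected))
  }

  structure(list(risk_table = tab, selected_id = selected,
                 selected_fit = fits[[selected]],
                 risk = risk, risk_source = risk_source,
                 risk_column = column,
                 split = list(train_idx = sp$train_idx,
                              test_idx = sp$test_idx),
                 nuisances = nuis, train_fraction = train_fraction,
                 nuisance_set = nuisance_set, seed = seed,
                 diagnostics = diagnostics, n = nrow(data),
                 n_candidates = length(fits)),
            class = "cate_select")
}

#' @export
print.cate_select <- function(x, ...) {
  cat("Causal model selection (train/test risk minimization)\n")
  cat(sprintf("  %d candidates, n = %d (train fraction %.2f, %s nuisance set)\n",
              x$n_candidates, x$n, x$train_fraction, x$nuisance_set))
  cat(sprintf("  selection risk: %s (%s)\n", x$risk,
              if (x$risk == "mu_risk") "factual" else x$risk_source))
  cat(sprintf("  selected: %s\n", x$selected_id))
  if (!is.null(x$diagnostics))
    cat(sprintf("  oracle check: excess tau-risk %.2f%% over the best candidate\n",
                x$diagnostics$excess_tau_risk))
  invisible(x)
}

#' @export
summary.cate_select <- function(object, ...) {
  tab <- object$risk_table
  cat("Risk table (", nrow(tab), " candidates)\n", sep = "")
  ord <- order(tab[[object$risk_column]])
  top <- utils::head(tab[ord, ], 5L)
  print(top, row.names = FALSE, digits = 4)
  if ("tau_risk_oracle" %in% names(tab)) {
    kappa <- kendall_tau(tab[[object$risk_column]], tab$tau_risk_oracle)
    cat(sprintf("\nKendall agreement of %s with the oracle tau-risk: %.3f\n",
                object$risk_column, kappa))
  }
  invisible(object)
}

#' @export
predict.cate_select <- function(object, newdata, ...) {
  predict_cate(object$selected_fit, newdata)
}

#' @export
coef.cate_select <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stop("supply 'newdata' (covariates) to average the CATE over",
         call. = FALSE)
  c(ate = estimate_ate(object$selected_fit, newdata))
}

#' @export
plot.cate_select <- function(x, ...) {
  tab <- x$risk_table
  if ("tau_risk_oracle" %in% names(tab)) {
    sel <- tab$candidate_id == x$selected_id
    graphics::plot(tab[[x$risk_column]], tab$tau_risk_oracle, log = "xy",
                   xlab = paste(x$risk_column, "(test set)"),
                   ylab = "oracle tau-risk (PEHE)",
                   main = "Selection risk vs oracle risk", ...)
    graphics::points(tab[[x$risk_column]][sel], tab$tau_risk_oracle[sel],
                     pch = 19, col = "red3")
    graphics::legend("topleft", legend = "selected", pch = 19, col = "red3",
                     bty = "n")
  } else {
    graphics::hist(tab[[x$risk_column]], breaks = 30,
                   xlab = x$risk_column, main = "Candidate risks")
  }
  invisible(x)
}
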