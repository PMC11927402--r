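# Benchmarking selection metrics against the oracle tau-risk across many
# simulated datasets: Kendall and relative-Kendall ranking agreement,
# excess tau-risk of each risk's selected model, and stratification by
# overlap (normalized total variation) and effect-to-baseline ratio.

#' Tie-adjusted Kendall rank correlation
#'
#' Kendall's tau-b between the orderings induced by two numeric vectors
#' (ties occur naturally with degenerate candidates, hence the
#' tie-adjusted variant).
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return scalar in [-1, 1].
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  if (length(x) < 2L)
    stop("Kendall correlation needs at least 2 observations", call. = FALSE)
  suppressWarnings(stats::cor(x, y, method = "kendall"))
}

#' Center per-risk Kendall agreements within a dataset
#'
#' Subtracts the across-risk mean from each risk's Kendall agreement, so
#' dataset-level difficulty cancels out; the centered values sum to zero.
#'
#' @param kappas named numeric vector (one Kendall agreement per risk,
#'   at least 2).
#' @return named numeric vector of the same length, mean zero.
#' @export
relative_kendall <- function(kappas) {
  kappas <- unlist(kappas)
  if (length(kappas) < 2L)
    stop("need at least 2 risks to compute relative agreement", call. = FALSE)
  kappas - mean(kappas)
}

#' Excess tau-risk of a selected candidate
#'
#' Relative gap, in percent, between the oracle tau-risk of the selected
#' candidate and the best achievable tau-risk in the table:
#' \eqn{100 (\tau\mathrm{risk}(sel) - \min_f) / \min_f}.
#'
#' @param risk_table a [compute_risk_table()] result containing the
#'   \code{tau_risk_oracle} column.
#' @param selected_id a \code{candidate_id} present in the table.
#' @return nonnegative scalar (percent). If the best tau-risk is exactly 0
#'   the absolute difference is returned instead, flagged with attribute
#'   \code{absolute = TRUE}.
#' @export
excess_tau_risk <- function(risk_table, selected_id) {
  if (!"tau_risk_oracle" %in% names(risk_table))
    stop("the risk table has no oracle tau-risk column", call. = FALSE)
  sel <- risk_table$candidate_id == selected_id
  if (!any(sel)) stop("unknown candidate id", call. = FALSE)
  best <- min(risk_table$tau_risk_oracle)
  gap <- risk_table$tau_risk_oracle[sel] - best
  if (best == 0) return(structure(gap, absolute = TRUE))
  100 * gap / best
}

#' Normalized total variation (NTV) overlap divergence
#'
#' Plug-in estimate of the total-variation distance between the treated and
#' control covariate densities, expressed through the propensity score:
#' \deqn{\mathrm{NTV} = \frac{1}{n}\sum_i \frac{1}{2}
#'   \left|\frac{e_i}{\bar p} - \frac{1 - e_i}{1 - \bar p}\right|}
#' with \eqn{\bar p} the treated prevalence. 0 means identical arm
#' densities (constant propensity); values near 1 mean separated supports
#' (weak overlap).
#'
#' @param e propensity vector, strictly inside (0, 1).
#' @param prevalence treated prevalence \eqn{\bar p}; defaults to
#'   \code{mean(e)}.
#' @return scalar in [0, 1].
#' @export
ntv_overlap <- function(e, prevalence = mean(e)) {
  if (any(e <= 0 | e >= 1))
    stop("'e' must be strictly inside (0, 1)", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("degenerate prevalence", call. = FALSE)
  clamp(mean(0.5 * abs(e / prevalence - (1 - e) / (1 - prevalence))), 0, 1)
}

#' Effect-to-baseline ratio
#'
#' Mean absolute ratio of the causal effect to the centered baseline
#' response,
#' \eqn{\Delta_\mu = \mathrm{mean}\,|(\mu_1 - \mu_0) / (\mu_0 + \mu_1 -
#' \overline{\mu_0 + \mu_1})|}, a scale-free measure of how large the
#' treatment effect is relative to baseline variation. Points whose
#' centered denominator is numerically zero are excluded; their count is
#' attached as attribute \code{n_excluded}.
#'
#' @param mu0,mu1 response-surface vectors.
#' @return nonnegative scalar with attribute \code{n_excluded}.
#' @export
effect_ratio <- function(mu0, mu1) {
  stopifnot(length(mu0) == length(mu1))
  s <- mu0 + mu1
  denom <- s - mean(s)
  tol <- 1e-9 * max(1, max(abs(denom)))
  keep <- abs(denom) > tol
  if (!any(keep))
    stop("degenerate baseline: all centered denominators are zero",
         call. = FALSE)
  structure(mean(abs((mu1[keep] - mu0[keep]) / denom[keep])),
            n_excluded = sum(!keep))
}

#' Tertile stratification
#'
#' Assigns each value to the first, second or third tertile of its
#' empirical distribution. Boundaries are half-open, lower-inclusive:
#' a value equal to a cut point falls in the upper stratum.
#'
#' @param values numeric vector (at least 3 values).
#' @param labels stratum labels in increasing order of \code{values}
#'   (e.g. \code{c("strong", "medium", "weak")} for an overlap divergence,
#'   where small divergence means strong overlap).
#' @return factor of stratum labels, with the cut points as attribute
#'   \code{cuts}.
#' @export
stratify_tertiles <- function(values,
                              labels = c("strong", "medium", "weak")) {
  if (length(values) < 3L)
    stop("need at least 3 values to form tertiles", call. = FALSE)
  stopifnot(length(labels) == 3L)
  cuts <- stats::quantile(values, c(1, 2) / 3, names = FALSE)
  idx <- 1L + (values >= cuts[1]) + (values >= cuts[2])
  structure(factor(labels[idx], levels = labels), cuts = cuts)
}

#' Benchmark selection risks against the oracle tau-risk
#'
#' Simulates \code{n_datasets} datasets from \code{config_sampler}, runs
#' the full selection procedure once per dataset, and scores every risk
#' column of the resulting risk tables against the oracle tau-risk:
#' Kendall agreement, relative (mean-centered) Kendall agreement, and the
#' excess tau-risk of each risk's selected candidate. Per-dataset overlap
#' (NTV) and effect ratio are recorded for stratification.
#'
#' @param n_datasets number of simulated datasets.
#' @param config_sampler function(seed) returning a [caussim_config()];
#'   default [caussim_config_sampler()].
#' @param family candidate family, default [build_caussim_family()].
#' @param train_fraction,nuisance_set,eta forwarded to [select_cate()].
#' @param seed master seed; each dataset gets an independent sub-seed.
#' @return object of class \code{"causal_benchmark"}: a data frame with
#'   one row per dataset (columns \code{dataset_id}, \code{ntv},
#'   \code{delta_mu}, \code{overlap_strength}, and per-risk
#'   \code{kendall_*}, \code{relative_kendall_*}, \code{excess_*}).
#'   Failed datasets are skipped with a warning and counted in attribute
#'   \code{n_failed}. \code{summary()} reports median and interquartile
#'   range per overlap stratum and risk.
#' @export
run_benchmark <- function(n_datasets, config_sampler = caussim_config_sampler(),
                          family = build_caussim_family(),
                          train_fraction = 0.9,
                          nuisance_set = c("shared", "separate"),
                          seed = 1L, eta = 1e-3) {
  stopifnot(n_datasets >= 1L)
  nuisance_set <- match.arg(nuisance_set)
  seeds <- derive_seeds(seed, paste0("ds", seq_len(n_datasets)))
  records <- vector("list", n_datasets)
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    rec <- tryCatch(
      benchmark_one(seeds[[i]], i, config_sampler, family, train_fraction,
                    nuisance_set, eta),
      error = function(e) {
        warning(sprintf("dataset %d failed: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(rec)) n_failed <- n_failed + 1L else records[[i]] <- rec
  }
  records <- do.call(rbind, records)
  if (is.null(records)) stop("every benchmark dataset failed", call. = FALSE)
  rownames(records) <- NULL
  attr(records, "n_failed") <- n_failed
  attr(records, "risks") <- sub("^kendall_", "",
                                grep("^kendall_", names(records), value = TRUE))
  class(records) <- c("causal_benchmark", "data.frame")
  records
}

benchmark_one <- function(seed, id, config_sampler, family, train_fraction,
                          nuisance_set, eta) {
  config <- config_sampler(seed)
  data <- sample_caussim(config)
  sel <- select_cate(data, family = family, risk = "r_risk",
                     train_fraction = train_fraction,
                     nuisance_set = nuisance_set, seed = seed, eta = eta)
  tab <- sel$risk_table
  risk_cols <- setdiff(names(tab), c("candidate_id", "tau_risk_oracle"))
  kappas <- vapply(risk_cols, function(col)
    kendall_tau(tab[[col]], tab$tau_risk_oracle), 0)
  excess <- vapply(risk_cols, function(col)
    as.numeric(excess_tau_risk(tab, select_best(tab, col))), 0)
  rel <- relative_kendall(kappas)
  out <- data.frame(dataset_id = id,
                    ntv = ntv_overlap(data$e),
                    delta_mu = as.numeric(effect_ratio(data$mu0, data$mu1)),
                    overlap_strength = config$overlap_strength)
  for (col in risk_cols) {
    out[[paste0("kendall_", col)]] <- kappas[[col]]
    out[[paste0("relative_kendall_", col)]] <- rel[[col]]
    out[[paste0("excess_", col)]] <- excess[[col]]
  }
  out
}

#' @export
summary.causal_benchmark <- function(object, ...) {
  risks <- attr(object, "risks")
  strata <- stratify_tertiles(object$ntv)
  rows <- list()
  for (s in levels(strata)) {
    sub <- object[strata == s, , drop = FALSE]
    for (r in risks) {
      k <- sub[[paste0("kendall_", r)]]
      ex <- sub[[paste0("excess_", r)]]
      rows[[paste(s, r)]] <- data.frame(
        overlap = s, risk = r, n = nrow(sub),
        kendall_median = stats::median(k),
        kendall_iqr = stats::IQR(k),
        excess_median = stats::median(ex),
        excess_iqr = stats::IQR(ex))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failed") <- attr(object, "n_failed")
  out
}

#' @export
print.causal_benchmark <- function(x, ...) {
  cat(sprintf("Causal model-selection benchmark: %d datasets (%d failed)\n",
              nrow(x), attr(x, "n_failed") %||% 0L))
  cat(sprintf("  NTV overlap range: [%.3f, %.3f]\n", min(x$ntv), max(x$ntv)))
  cat("  risks scored:", paste(attr(x, "risks"), collapse = ", "), "\n")
  cat("Use summary() for per-stratum medians.\n")
  invisible(x)
}
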