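# The bin-averaging experiment: simulate DNM counts under the fitted
# MI model with added unexplained per-site variance (upsilon) and measure
# how often the simulated log(rate)-vs-MI correlation exceeds the observed
# one. Because each MI bin averages over n sites, per-site variance upsilon
# enters the bin mean only as upsilon/n — large cryptic variance can hide
# behind an excellent binned correlation.

#' Simulation configuration
#'
#' @param upsilon unexplained per-site rate variance (dimensionless, >= 0):
#'   variance of the mean-one multiplicative factor on each site's rate.
#' @param n_reps number of simulated datasets (default 1000).
#' @param seed optional integer master seed.
#' @param bootstrap_regression refit the rate model on a bootstrap resample
#'   of the bins in each replicate, propagating regression uncertainty
#'   (default `TRUE`).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(upsilon, n_reps = 1000L, seed = NULL,
                              bootstrap_regression = TRUE) {
  if (upsilon < 0) stopf("upsilon must be >= 0")
  if (n_reps < 1) stopf("n_reps must be >= 1")
  structure(
    list(upsilon = upsilon, n_reps = as.integer(n_reps), seed = seed,
         bootstrap_regression = isTRUE(bootstrap_regression)),
    class = "simulation_config")
}

#' Expected DNM counts per bin under a fitted rate model
#'
#' `Z = n * base^(a + b * mi_mid)` for each bin: the expected number of
#' mutations among the bin's `n` sites if the model explained all rate
#' variation.
#'
#' @param fit an `mi_fit`.
#' @param bins an `mi_bins` table sharing the fit's MI space.
#' @return a `data.frame` with columns `mi_mid`, `n`, `Z`.
#' @export
predict_expected_counts <- function(fit, bins) {
  stopifnot(inherits(fit, "mi_fit"))
  check_bins(bins, min_bins = 1L, need_positive_d = FALSE)
  Z <- bins$n * fit$log_base^(fit$intercept + fit$slope * bins$mi_mid)
  data.frame(mi_mid = bins$mi_mid, n = bins$n, Z = Z)
}

#' Simulate observed DNM counts with unexplained variance
#'
#' For each bin, the expected count `Z` is multiplied by a mean-one
#' lognormal factor with variance `upsilon / n` (the variance left after
#' averaging per-site factors of variance `upsilon` over the bin's `n`
#' sites) and an observed count is drawn from a Poisson with that mean.
#' `upsilon = 0` is exact Poisson sampling (factor identically 1).
#'
#' @param expected output of [predict_expected_counts()].
#' @param upsilon unexplained per-site variance (>= 0).
#' @return integer vector of simulated counts, one per bin. Uses the
#'   current RNG state; seed via the caller (e.g. [run_table1()]).
#' @export
simulate_counts <- function(expected, upsilon) {
  stopifnot(all(c("n", "Z") %in% names(expected)))
  if (upsilon < 0) stopf("upsilon must be >= 0")
  if (any(expected$Z < 0)) stopf("expected counts Z must be non-negative")
  if (any(expected$n <= 0)) stopf("bin site counts n must be positive")
  m <- nrow(expected)
  factor <- if (upsilon == 0) rep(1, m) else
    rlnorm_mean_one(m, upsilon / expected$n)
  stats::rpois(m, expected$Z * factor)
}

#' Proportion of simulated datasets with a stronger correlation
#'
#' The core experiment: take the observed bins and their fitted rate model,
#' repeatedly simulate DNM counts under that model plus unexplained
#' variance `upsilon`, and record the Pearson correlation between
#' `log(simulated d / n)` and MI. Replicates in which any bin draws zero
#' DNMs are removed (the log rate is undefined). When
#' `bootstrap_regression` is on, each replicate first refits the model on a
#' bootstrap resample of the bins to propagate regression uncertainty.
#'
#' @param bins an `mi_bins` table (>= 3 bins, all `d > 0`).
#' @param fit the `mi_fit` obtained from those bins.
#' @param config a [simulation_config()].
#' @return a list of class `table1_sim`: `r_values` (kept replicates'
#'   correlations), `r_observed`, `proportion_greater` (fraction of kept
#'   replicates with `r > r_observed`, strict), `n_dropped`, `n_reps`,
#'   `upsilon`.
#' @export
run_table1 <- function(bins, fit, config) {
  check_bins(bins)
  stopifnot(inherits(fit, "mi_fit"), inherits(config, "simulation_config"))
  log_y <- log(bins$z)
  r_observed <- stats::cor(bins$mi_mid, log_y)
  with_seed(config$seed, {
    r_values <- numeric(0)
    n_dropped <- 0L
    for (rep_i in seq_len(config$n_reps)) {
      rep_fit <- if (config$bootstrap_regression) {
        idx <- resample_bin_rows(nrow(bins), bins$mi_mid)
        fit_loglinear(bins[idx, , drop = FALSE], log_base = fit$log_base,
                      weighting = fit$weighting)
      } else {
        fit
      }
      expected <- predict_expected_counts(rep_fit, bins)
      d_sim <- simulate_counts(expected, config$upsilon)
      if (any(d_sim == 0L)) {
        n_dropped <- n_dropped + 1L
      } else {
        r_values <- c(r_values, stats::cor(bins$mi_mid, log(d_sim / bins$n)))
      }
    }
    if (length(r_values) == 0L) {
      stopf(paste("all %d replicates produced a zero-count bin;",
                  "expected counts are too small"), config$n_reps)
    }
    structure(
      list(r_values = r_values, r_observed = r_observed,
           proportion_greater = mean(r_values > r_observed),
           n_dropped = n_dropped, n_reps = config$n_reps,
           upsilon = config$upsilon),
      class = "table1_sim")
  })
}

#' @export
print.table1_sim <- function(x, ...) {
  cat(sprintf(
    "upsilon = %g: %d/%d replicates kept, r_obs = %.4f, P(r_sim > r_obs) = %.3f\n",
    x$upsilon, length(x$r_values), x$n_reps, x$r_observed,
    x$proportion_greater))
  invisible(x)
}

#' Sweep the unexplained variance
#'
#' Runs [run_table1()] once per `upsilon` value with independent seed
#' substreams derived from the master seed, so the sweep is reproducible
#' and order-independent.
#'
#' @inheritParams run_table1
#' @param upsilons numeric vector of variance values (>= 0).
#' @return a `data.frame` with one row per upsilon: `upsilon`,
#'   `proportion_greater`, `n_kept`, `n_dropped`, `r_observed`.
#' @export
upsilon_sweep <- function(bins, fit, upsilons, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(upsilons) == 0) stopf("upsilons must be non-empty")
  sub_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L,
                                    length(upsilons)))
  rows <- lapply(seq_along(upsilons), function(i) {
    cfg <- simulation_config(upsilons[i], n_reps = config$n_reps,
                             seed = sub_seeds[i],
                             bootstrap_regression =
                               config$bootstrap_regression)
    res <- run_table1(bins, fit, cfg)
    data.frame(upsilon = upsilons[i],
               proportion_greater = res$proportion_greater,
               n_kept = length(res$r_values), n_dropped = res$n_dropped,
               r_observed = res$r_observed)
  })
  do.call(rbind, rows)
}

#' Coefficient of variation implied by an unexplained variance
#'
#' For a mean-one rate factor with variance `upsilon`, the coefficient of
#' variation is simply `sqrt(upsilon)` — a scale-free way to express how
#' violently per-site rates would have to vary for the variance to be
#' noticeable after bin-averaging.
#'
#' @param upsilon variance (>= 0).
#' @return `sqrt(upsilon)`.
#' @export
cv_of_lognormal <- function(upsilon) {
  if (any(upsilon < 0)) stopf("upsilon must be >= 0")
  sqrt(upsilon)
}
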