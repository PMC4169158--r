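# Binning DNMs by MI and fitting the weighted log-linear rate model
# log(z) = a + b * MI, where z = d/n is DNMs per site within an MI bin.
# Also: quadratic-term test, slope comparison between datasets, and the
# bin-level bootstrap used to propagate regression uncertainty.

#' Bin a DNM dataset by mutability index
#'
#' Tiles the track's MI range with half-open intervals `[lo, lo + bin_width)`
#' and aggregates site counts `n` and DNM counts `d` per bin; bins with
#' `d <= min_dnm` DNMs are removed (there are too few DNMs at rare MI
#' values for a per-value rate to be stable). `mi_mid` is the
#' site-count-weighted mean MI within the bin and `z = d/n` the observed
#' per-site mutation rate.
#'
#' @param dnms a `dnm_dataset` (needs a `mi` column).
#' @param track the companion [mi_track()]; every DNM's MI must be present.
#' @param bin_width width of the MI bins (default 10).
#' @param min_dnm bins with `d <= min_dnm` are dropped (default 5).
#' @return a `data.frame` of class `mi_bins` with columns
#'   `mi_mid`, `n`, `d`, `z`.
#' @examples
#' tr <- make_mi_track(1e5, seed = 1)
#' dn <- sample_dnms(tr, true_rate_model(-1, 0.01), 650, seed = 2)
#' bin_by_mi(dn, tr)
#' @export
bin_by_mi <- function(dnms, track, bin_width = 10L, min_dnm = 5L) {
  stopifnot(inherits(track, "mi_track"))
  if (bin_width < 1) stopf("bin_width must be >= 1")
  bad <- setdiff(unique(dnms$mi), track$mi)
  if (length(bad) > 0) {
    stopf("DNM MI value(s) not present in track: %s",
          paste(utils::head(sort(bad), 5L), collapse = ", "))
  }
  if (nrow(track) == 0) return(empty_bins())
  lo0 <- floor(min(track$mi) / bin_width) * bin_width
  bin_of <- function(mi) floor((mi - lo0) / bin_width)
  track_bin <- bin_of(track$mi)
  d <- tapply(rep(1L, nrow(dnms)), factor(bin_of(dnms$mi),
                                          levels = sort(unique(track_bin))),
              sum, default = 0L)
  n <- tapply(track$n_sites, factor(track_bin), sum)
  mi_mid <- tapply(seq_len(nrow(track)), factor(track_bin), function(i) {
    stats::weighted.mean(track$mi[i], track$n_sites[i])
  })
  out <- data.frame(mi_mid = as.numeric(mi_mid), n = as.numeric(n),
                    d = as.integer(d))
  out <- out[out$n > 0 & out$d > min_dnm, , drop = FALSE]
  out$z <- out$d / out$n
  rownames(out) <- NULL
  class(out) <- c("mi_bins", "data.frame")
  out
}

empty_bins <- function() {
  out <- data.frame(mi_mid = numeric(0), n = numeric(0), d = integer(0),
                    z = numeric(0))
  class(out) <- c("mi_bins", "data.frame")
  out
}

check_bins <- function(bins, min_bins = 3L, need_positive_d = TRUE) {
  stopifnot(is.data.frame(bins),
            all(c("mi_mid", "n", "d", "z") %in% names(bins)))
  if (nrow(bins) < min_bins) {
    stopf("need at least %d bins, got %d", min_bins, nrow(bins))
  }
  if (need_positive_d && any(bins$d <= 0)) {
    stopf("all bins must have d > 0 (log rate undefined); filter first")
  }
  invisible(bins)
}

fit_weights <- function(bins, weighting = c("dnm", "equal")) {
  weighting <- match.arg(weighting)
  if (weighting == "dnm") as.numeric(bins$d) else rep(1, nrow(bins))
}

#' Weighted log-linear fit of mutation rate against MI
#'
#' Weighted least squares of `log(z, log_base)` on `mi_mid`. The default
#' weighting by DNM count `d` is the delta-method inverse variance of
#' `log z` under Poisson counts (`Var[log z] ~ 1/d`); equal weights are
#' available for sensitivity. The Pearson correlation `r` is computed on
#' the same (unweighted) binned points, as plotted.
#'
#' @param bins an `mi_bins` table with >= 3 bins, all `d > 0`.
#' @param log_base base of the log transform (default 10). Slopes are per
#'   MI unit in this base; predictions invert with the stored base.
#' @param weighting `"dnm"` (weight = d) or `"equal"`.
#' @return an object of class `mi_fit`: a list with `intercept`, `slope`,
#'   `se_intercept`, `se_slope`, `r`, `log_base`, `weighting`, `n_bins`,
#'   and `degenerate` (`TRUE` when the response is constant, in which case
#'   `slope = 0` and `r` is reported as 0).
#' @export
fit_loglinear <- function(bins, log_base = 10, weighting = c("dnm", "equal")) {
  check_bins(bins)
  check_log_base(log_base)
  weighting <- match.arg(weighting)
  w <- fit_weights(bins, weighting)
  y <- log_b(bins$z, log_base)
  degenerate <- isTRUE(all.equal(stats::var(y), 0)) || stats::var(y) == 0
  fm <- stats::lm(y ~ mi_mid, data = data.frame(mi_mid = bins$mi_mid, y = y),
                  weights = w)
  # exact fits (collinear bins) are legitimate inputs here; silence
  # summary.lm's perfect-fit warning
  cf <- suppressWarnings(summary(fm))$coefficients
  r <- if (degenerate) 0 else stats::cor(bins$mi_mid, y)
  structure(
    list(intercept = unname(cf[1, 1]), slope = unname(cf[2, 1]),
         se_intercept = unname(cf[1, 2]), se_slope = unname(cf[2, 2]),
         r = r, log_base = log_base, weighting = weighting,
         n_bins = nrow(bins), degenerate = degenerate,
         quad_coeff = NULL, quad_p = NULL),
    class = "mi_fit")
}

#' Add a quadratic MI term and test its significance
#'
#' Fits `log(z) = a + b*MI + c*MI^2` by the same weighted least squares and
#' reports the two-sided t-test p-value of the quadratic coefficient — the
#' check for curvature in the rate-vs-MI relationship.
#'
#' @inheritParams fit_loglinear
#' @return an `mi_fit` whose `slope` is the linear coefficient and whose
#'   `quad_coeff`/`quad_p` hold the quadratic term and its p-value. On an
#'   exactly collinear input the residual variance is 0 and the t-test is
#'   undefined; a vanishing quadratic coefficient is then reported with
#'   `quad_p = 1`.
#' @export
fit_quadratic <- function(bins, log_base = 10, weighting = c("dnm", "equal")) {
  check_bins(bins, min_bins = 4L)
  check_log_base(log_base)
  weighting <- match.arg(weighting)
  w <- fit_weights(bins, weighting)
  y <- log_b(bins$z, log_base)
  dat <- data.frame(mi_mid = bins$mi_mid, mi_sq = bins$mi_mid^2, y = y)
  fm <- stats::lm(y ~ mi_mid + mi_sq, data = dat, weights = w)
  sm <- suppressWarnings(summary(fm))
  cf <- sm$coefficients
  quad_coeff <- unname(cf["mi_sq", 1])
  quad_p <- unname(cf["mi_sq", 4])
  scale <- max(abs(y), 1)
  if (!is.finite(quad_p) || sm$sigma < 1e-8 * scale) {
    # exact (zero-residual) fit: the t-test is numerical noise; a vanishing
    # quadratic coefficient is then simply "no curvature"
    quad_p <- if (abs(quad_coeff) < 1e-10 * scale) 1 else NA_real_
  }
  structure(
    list(intercept = unname(cf[1, 1]), slope = unname(cf[2, 1]),
         se_intercept = unname(cf[1, 2]), se_slope = unname(cf[2, 2]),
         r = stats::cor(bins$mi_mid, y), log_base = log_base,
         weighting = weighting, n_bins = nrow(bins), degenerate = FALSE,
         quad_coeff = quad_coeff, quad_p = quad_p),
    class = "mi_fit")
}

#' @export
print.mi_fit <- function(x, ...) {
  cat(sprintf("log%s(z) = %.4g + %.4g * MI  (se %.2g, %.2g), r = %.3f, %d bins\n",
              if (abs(x$log_base - exp(1)) < 1e-12) "e" else
                format(x$log_base), x$intercept, x$slope,
              x$se_intercept, x$se_slope, x$r, x$n_bins))
  if (!is.null(x$quad_coeff)) {
    cat(sprintf("  quadratic term %.3g (p = %.3g)\n", x$quad_coeff, x$quad_p))
  }
  if (isTRUE(x$degenerate)) cat("  [degenerate fit: constant response]\n")
  invisible(x)
}

#' Compare the slopes of two independent fits
#'
#' Two-sided z-test on the slope difference,
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` — used to ask whether one DNM
#' dataset shows a significantly shallower rate-vs-MI relationship than
#' another (e.g. through under-reporting of mutable sites).
#'
#' @param fit1,fit2 `mi_fit` objects in the same log base.
#' @return a list with `z_statistic` (negative when `fit1`'s slope is
#'   smaller) and `p_value`.
#' @export
compare_slopes <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "mi_fit"), inherits(fit2, "mi_fit"))
  if (abs(fit1$log_base - fit2$log_base) > 1e-12) {
    stopf("fits use different log bases (%g vs %g)",
          fit1$log_base, fit2$log_base)
  }
  if (!all(is.finite(c(fit1$slope, fit2$slope, fit1$se_slope,
                       fit2$se_slope)))) {
    stopf("both fits need finite slopes and standard errors")
  }
  z <- (fit1$slope - fit2$slope) / sqrt(fit1$se_slope^2 + fit2$se_slope^2)
  list(z_statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# Resample bin rows with replacement, requiring >= min_distinct distinct
# mi_mid values so the refit is identified.
resample_bin_rows <- function(n_bins, mi_mid, min_distinct = 3L,
                              max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    idx <- sample.int(n_bins, n_bins, replace = TRUE)
    if (length(unique(mi_mid[idx])) >= min_distinct) return(idx)
  }
  stopf("could not draw a bootstrap resample with %d distinct MI values",
        min_distinct)
}

#' Bootstrap the log-linear regression over bins
#'
#' Resamples the regression points (bins) with replacement and refits;
#' replicates with fewer than 3 distinct MI values are redrawn. This is the
#' uncertainty-propagation step for the fitted rate-MI relationship.
#'
#' @inheritParams fit_loglinear
#' @param n_boot number of bootstrap replicates (> 0).
#' @param seed optional integer seed.
#' @return a list of `n_boot` `mi_fit` objects.
#' @export
bootstrap_fit <- function(bins, n_boot, log_base = 10,
                          weighting = c("dnm", "equal"), seed = NULL) {
  check_bins(bins)
  if (n_boot <= 0) stopf("n_boot must be positive")
  weighting <- match.arg(weighting)
  with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      idx <- resample_bin_rows(nrow(bins), bins$mi_mid)
      fit_loglinear(bins[idx, , drop = FALSE], log_base = log_base,
                    weighting = weighting)
    })
  })
}
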