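test_that("binning applies the removal rule at its boundary and conserves DNMs", {
  track <- mi_track(0:19, rep(100, 20))
  dnms <- data.frame(chrom = "chr1", pos = 1:11,
                     mi = c(0L, 1L, 2L, 3L, 4L, 5L, 10L, 11L, 12L, 13L, 14L),
                     study = "x")
  bins <- bin_by_mi(dnms, track)
  # the d = 5 bin is removed (5 <= 5); the d = 6 bin stays
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$d, 6L)
  expect_equal(bins$n, 1000)
  expect_equal(bins$z, 0.006)
  expect_equal(bins$mi_mid, 4.5)

  # empty input => empty bin table
  expect_equal(nrow(bin_by_mi(dnms[0, ], track)), 0L)

  # an MI absent from the track is an error naming the value
  bad <- dnms
  bad$mi[1] <- 25L
  expect_error(bin_by_mi(bad, track), "25")

  # retained + dropped = total on a synthetic dataset
  case <- synth_case(31, n_dnm = 2e4)
  all_bins <- bin_by_mi(case$dnms, case$track, min_dnm = -1L)
  expect_equal(sum(all_bins$d), nrow(case$dnms))
  expect_lte(sum(case$bins$d), nrow(case$dnms))
})

test_that("an exact log-linear relationship is recovered exactly", {
  bins <- exact_line_bins()
  fit <- fit_loglinear(bins, log_base = 10)
  expect_equal(fit$slope, 0.1, tolerance = 1e-10)
  expect_equal(fit$intercept, -10.5, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  # equal-weight fit agrees with the closed-form OLS solution
  set.seed(4)
  rb <- make_bins(mi_mid = seq(0, 110, by = 10), n = 1e6,
                  d = rpois(12, 200 * exp(0.02 * seq(0, 110, by = 10))))
  f_eq <- fit_loglinear(rb, weighting = "equal")
  x <- rb$mi_mid
  y <- log10(rb$z)
  b_ols <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(f_eq$slope, b_ols, tolerance = 1e-10)
  expect_equal(f_eq$intercept, mean(y) - b_ols * mean(x), tolerance = 1e-10)

  # fewer than 3 bins, or a zero count, refuse to fit
  expect_error(fit_loglinear(rb[1:2, ]), "at least 3")
  rb0 <- rb
  rb0$d[1] <- 0L
  expect_error(fit_loglinear(rb0), "d > 0")
})

test_that("the correlation is invariant to log base and affine MI rescaling", {
  case <- synth_case(41)
  f10 <- fit_loglinear(case$bins, log_base = 10)
  fe <- fit_loglinear(case$bins, log_base = exp(1))
  expect_equal(f10$r, fe$r, tolerance = 1e-12)
  # slopes convert by ln(10)
  expect_equal(fe$slope, f10$slope * log(10), tolerance = 1e-10)

  shifted <- case$bins
  shifted$mi_mid <- 2 * shifted$mi_mid + 7
  expect_equal(fit_loglinear(shifted)$r, f10$r, tolerance = 1e-12)
})

test_that("a constant response is reported as a degenerate zero-slope fit", {
  bins <- make_bins(mi_mid = c(10, 20, 30), n = 1e6, d = c(100L, 100L, 100L))
  fit <- fit_loglinear(bins)
  expect_true(fit$degenerate)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$r, 0)
})

test_that("the quadratic term is detected when present and null when absent", {
  # exact line: vanishing coefficient, p reported as 1
  fq0 <- fit_quadratic(rbind(exact_line_bins(),
                             make_bins(35, 1e12, 1e5)))
  expect_lt(abs(fq0$quad_coeff), 1e-12)
  expect_equal(fq0$quad_p, 1)

  # built-in curvature at 12 bins with small noise
  set.seed(5)
  mi <- seq(5, 115, by = 10)
  log_z <- -10 + 0.01 * mi - 1e-4 * mi^2 + rnorm(12, 0, 0.01)
  n <- rep(1e12, 12)
  d <- pmax(1L, as.integer(round(n * 10^log_z)))
  bins <- make_bins(mi, n, d)
  fq <- fit_quadratic(bins)
  expect_lt(fq$quad_coeff, 0)
  expect_lt(fq$quad_p, 0.05)

  expect_error(fit_quadratic(exact_line_bins()), "at least 4")
})

test_that("slope comparison gives a two-sided normal test", {
  case <- synth_case(51)
  fit <- fit_loglinear(case$bins)
  same <- compare_slopes(fit, fit)
  expect_equal(same$z_statistic, 0)
  expect_equal(same$p_value, 1)

  mk_fit <- function(slope, se) {
    f <- fit
    f$slope <- slope
    f$se_slope <- se
    f
  }
  # published-style slopes: Kong-like vs Michaelson-like
  kong <- mk_fit(0.0047, 0.0006)
  mich <- mk_fit(0.010, 0.0007)
  cmp <- compare_slopes(kong, mich)
  expect_lt(cmp$z_statistic, 0)
  expect_gt(abs(cmp$z_statistic), 3.3)
  expect_lt(cmp$p_value, 0.001)

  # independent normal-tail oracle (complementary error function)
  a <- mk_fit(0.010, 0.0007)
  b <- mk_fit(0.0084, 0.0007)
  cmp2 <- compare_slopes(a, b)
  expect_equal(cmp2$p_value,
               pracma::erfc(abs(cmp2$z_statistic) / sqrt(2)),
               tolerance = 1e-12)

  base_e <- fit_loglinear(case$bins, log_base = exp(1))
  expect_error(compare_slopes(fit, base_e), "log base")
})

test_that("bootstrap refits are collinear-stable, seeded, and calibrated", {
  line <- rbind(exact_line_bins(), make_bins(35, 1e12, 1e5))
  boots <- bootstrap_fit(line, 50, seed = 61)
  expect_true(all(abs(vapply(boots, `[[`, numeric(1), "slope") - 0.1) < 1e-10))

  case <- synth_case(62)
  b1 <- bootstrap_fit(case$bins, 20, seed = 63)
  b2 <- bootstrap_fit(case$bins, 20, seed = 63)
  expect_identical(vapply(b1, `[[`, numeric(1), "slope"),
                   vapply(b2, `[[`, numeric(1), "slope"))
  expect_error(bootstrap_fit(case$bins, 0), "positive")

  # central 95% of bootstrap slopes covers the generating slope in >= 90%
  # of outer replicates
  covered <- vapply(seq_len(50), function(i) {
    case_i <- synth_case(100 + i)
    slopes <- vapply(bootstrap_fit(case_i$bins, 200, seed = 200 + i),
                     `[[`, numeric(1), "slope")
    ci <- stats::quantile(slopes, c(0.025, 0.975))
    ci[1] <= 0.01 && 0.01 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
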