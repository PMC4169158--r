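test_that("the coincidence kernel has the right values and limits", {
  expect_equal(mutation_kernel(0, 0.01), 0)
  expect_equal(mutation_kernel(1, 0.01), 1.0098511604424128,
               tolerance = 1e-12)
  # hypermutable sites destroy themselves: only ancestral sharing survives
  expect_equal(mutation_kernel(1e6, 0.01), 1, tolerance = 1e-9)
  expect_error(mutation_kernel(-1, 0.01), ">= 0")
  expect_error(mutation_kernel(1, 0), "> 0")
})

test_that("degenerate and small-divergence limits match gamma moments", {
  # a point mass at gamma = 1
  for (v in c(0.0092, 0.092)) {
    m <- gamma_rate_model(1e9, v)
    expect_equal(coincident_integral(m), mutation_kernel(1, v),
                 tolerance = 1e-6)
    expect_equal(excess_ratio(m), 1, tolerance = 1e-6)
    expect_equal(mean_fold_q(m), 1, tolerance = 1e-6)
  }
  # v -> 0: excess -> E[gamma^2] = 1 + 1/a and Q -> E[gamma^3]/E[gamma^2]
  for (a in c(0.5, 1, 2)) {
    m <- gamma_rate_model(a, 1e-8)
    expect_equal(excess_ratio(m), 1 + 1 / a, tolerance = 1e-4)
    expect_equal(mean_fold_q(m), (a + 2) / a, tolerance = 1e-4)
  }
})

test_that("quadrature agrees with closed-form and Monte-Carlo oracles", {
  for (a in c(0.5, 1, 2)) {
    for (v in c(0.0092, 0.092)) {
      m <- gamma_rate_model(a, v)
      # closed form E[gamma^k e^{-c gamma}] assembled from gamma moments
      expect_equal(coincident_integral(m), cf_coincident_integral(a, v),
                   tolerance = 1e-9)
      expect_equal(mean_fold_q(m), cf_mean_fold_q(a, v), tolerance = 1e-9)

      # Monte-Carlo oracle on the same integrals
      set.seed(1000 + round(100 * a + 1000 * v))
      g <- rgamma(1e6, shape = a, rate = a)
      k <- mutation_kernel(g, v)
      for (pair in list(list(mc = k, quad = coincident_integral(m)),
                        list(mc = k * g,
                             quad = mean_fold_q(m) * coincident_integral(m)))) {
        se <- sd(pair$mc) / sqrt(length(pair$mc))
        expect_lt(abs(mean(pair$mc) - pair$quad), 3 * se)
      }
    }
  }
})

test_that("excess and Q decrease in shape; inversion round-trips", {
  grid <- c(0.5, 1, 2, 4, 8)
  for (v in c(0.0092, 0.092)) {
    ex <- vapply(grid, function(a) excess_ratio(gamma_rate_model(a, v)),
                 numeric(1))
    qq <- vapply(grid, function(a) mean_fold_q(gamma_rate_model(a, v)),
                 numeric(1))
    expect_true(all(diff(ex) < 0))
    expect_true(all(diff(qq) < 0))
    expect_true(all(ex >= 1) && all(qq >= 1))
  }

  # round trip excess_ratio(fit_gamma_shape(x)) = x
  for (x in c(1.01, 1.1, 1.5, 2, 3)) {
    a_hat <- fit_gamma_shape(x, 0.0092)
    expect_equal(excess_ratio(gamma_rate_model(a_hat, 0.0092)), x,
                 tolerance = 1e-8)
  }
  for (x in c(1.01, 1.5, 2)) {
    a_hat <- fit_gamma_shape(x, 0.092)
    expect_equal(excess_ratio(gamma_rate_model(a_hat, 0.092)), x,
                 tolerance = 1e-8)
  }

  # small-v closed form: excess = 1 + 1/a inverts to a
  for (a0 in c(0.5, 1, 2)) {
    expect_equal(fit_gamma_shape(1 + 1 / a0, 1e-8), a0, tolerance = 1e-4)
  }

  expect_error(fit_gamma_shape(0.9, 0.0092), "> 1")
  expect_error(fit_gamma_shape(10, 0.092), "attainable")
})

test_that("fold estimates increase with the excess and bracket their CI", {
  folds <- vapply(c(1.05, 1.2, 1.5, 2), function(x) {
    fold_from_excess(x, 0.0092)$q_fold
  }, numeric(1))
  expect_true(all(diff(folds) > 0))
  expect_true(all(folds >= 1))

  est <- fold_from_excess(1.83, 0.0092, excess_ci = c(1.80, 1.86))
  expect_lte(est$ci_low, est$q_fold)
  expect_lte(est$q_fold, est$ci_high)
  expect_gt(est$q_fold, 1)
  # near-unity excess: continuity at the no-variation boundary
  expect_lt(fold_from_excess(1.001, 0.0092)$q_fold, 1.01)
  expect_error(fold_from_excess(1.2, 0.0092, excess_ci = c(0.9, 1.3)),
               "> 1")
})

test_that("predicted folds and the MI permutation test behave", {
  fit <- structure(
    list(intercept = -10, slope = 0.01, se_intercept = 0.1,
         se_slope = 0.001, r = NA_real_, log_base = 10, weighting = "dnm",
         n_bins = 10L, degenerate = FALSE, quad_coeff = NULL, quad_p = NULL),
    class = "mi_fit")
  expect_equal(predicted_fold_from_fit(fit, c(1, 5, 9), c(1, 5, 9)), 1)
  # singleton sets: exact closed form 10^(b * (91.6 - 81.4))
  expect_equal(predicted_fold_from_fit(fit, 91.6, 81.4), 10^(0.01 * 10.2),
               tolerance = 1e-12)
  # Jensen: a mean-preserving spread plus shift beats the pure-shift fold
  set.seed(7)
  b_set <- rnorm(500, 0, 5)
  delta <- 10
  a_set <- mean(b_set) + 3 * (b_set - mean(b_set)) + delta
  expect_gte(predicted_fold_from_fit(fit, a_set, b_set),
             10^(fit$slope * delta))
  expect_error(predicted_fold_from_fit(fit, numeric(0), 1), "non-empty")

  same <- compare_mi_sets(c(1, 2, 3, 4), c(1, 2, 3, 4), n_perm = 500,
                          seed = 1)
  expect_equal(same$mean_a, same$mean_b)
  expect_gt(same$p_value, 0.9)

  set.seed(8)
  lo <- rnorm(1000)
  hi <- rnorm(1000) + 10
  shifted <- compare_mi_sets(hi, lo, n_perm = 1e4, seed = 2)
  expect_lte(shifted$p_value, 0.001)
  expect_identical(shifted, compare_mi_sets(hi, lo, n_perm = 1e4, seed = 2))
  expect_error(compare_mi_sets(hi, lo, n_perm = 50), ">= 100")
})
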