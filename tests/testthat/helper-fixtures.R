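# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored data.

# Three exactly collinear bins on log10(z) = -10.5 + 0.1 * MI, with integer
# DNM counts so z = d/n holds exactly.
exact_line_bins <- function() {
  out <- data.frame(mi_mid = c(5, 15, 25),
                    n = rep(1e12, 3),
                    d = c(100L, 1000L, 10000L))
  out$z <- out$d / out$n
  class(out) <- c("mi_bins", "data.frame")
  out
}

make_bins <- function(mi_mid, n, d) {
  out <- data.frame(mi_mid = mi_mid, n = n, d = as.integer(d))
  out$z <- out$d / out$n
  class(out) <- c("mi_bins", "data.frame")
  out
}

# A synthetic DNM study: genome-like track, log-linear generating model,
# binned and ready to fit.
synth_case <- function(seed, n_total = 2e5, intercept = -2.5, slope = 0.01,
                       n_dnm = 650, cryptic_variance = 0) {
  track <- make_mi_track(n_total, seed = seed)
  model <- true_rate_model(intercept, slope,
                           cryptic_variance = cryptic_variance)
  dnms <- sample_dnms(track, model, n_dnm, seed = seed + 1L)
  bins <- bin_by_mi(dnms, track)
  list(track = track, model = model, dnms = dnms, bins = bins)
}

# Closed-form moments of the mean-one gamma (shape a, rate a):
# E[gamma^k exp(-c*gamma)] = a^a * Gamma(a+k) / (Gamma(a) * (a+c)^(a+k)),
# computed on the log scale for stability. Independent of the quadrature
# path in R/coincident-theory.R.
gamma_exp_moment <- function(a, k, c) {
  exp(a * log(a) + lgamma(a + k) - lgamma(a) - (a + k) * log(a + c))
}

# Closed-form denominator and numerator of the coincidence integrals.
cf_coincident_integral <- function(a, v) {
  gamma_exp_moment(a, 2, v) + 1 - exp(a * (log(a) - log(a + 2 * v)))
}
cf_q_numerator <- function(a, v) {
  gamma_exp_moment(a, 3, v) + 1 - gamma_exp_moment(a, 1, 2 * v)
}
cf_mean_fold_q <- function(a, v) cf_q_numerator(a, v) / cf_coincident_integral(a, v)
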