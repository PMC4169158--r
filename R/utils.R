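# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' If `seed` is `NULL` the expression runs under the current RNG state;
#' otherwise the global RNG state is restored afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Draw mean-one lognormal variates with a given variance
#'
#' The unique lognormal with mean 1 and variance `variance` has log-scale
#' variance \eqn{\sigma^2 = \log(1 + V)} and log-scale mean \eqn{-\sigma^2/2}.
#' This is the multiplicative factor used to model per-site mutation-rate
#' variance unexplained by a mutability model: averaged over n sites its
#' variance shrinks to approximately V/n.
#'
#' @param n number of draws.
#' @param variance variance V >= 0; scalar or vector recycled against `n`.
#'   `variance = 0` returns exact ones.
#' @return numeric vector of length `n`, each draw positive with mean 1.
#' @examples
#' x <- rlnorm_mean_one(1e4, 2)
#' c(mean(x), var(x)) # close to (1, 2)
#' @export
rlnorm_mean_one <- function(n, variance) {
  if (any(variance < 0)) stopf("variance must be >= 0")
  if (length(variance) == 1L && variance == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(variance))
  out <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  # exact ones where variance is zero (vectorised case)
  if (length(variance) > 1L) out[rep_len(variance == 0, n)] <- 1
  out
}

# log to an arbitrary base, validated once at model construction
log_b <- function(x, base) log(x) / log(base)

check_log_base <- function(log_base) {
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 0 ||
      log_base == 1) {
    stopf("log_base must be a single positive number != 1 (use 10 or exp(1))")
  }
  log_base
}
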