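# Synthetic-data generators: MI tracks, DNM datasets, and two-species
# coincident-SNP tables with the statistical structure the downstream
# analyses assume. Real inputs (published DNM supplements, a genome-wide MI
# track, curated human-chimp SNPs) are external; everything here is built to
# be distributionally faithful so the pipeline is testable end to end.

#' Construct an MI site track
#'
#' A track records, for each integer mutability-index (MI) value, how many
#' genomic sites carry that value. It plays the role of the genome-wide
#' per-MI site counts `n` against which DNM counts are rated.
#'
#' @param mi integer vector of unique MI values.
#' @param n_sites non-negative integer site counts, same length as `mi`.
#' @return a `data.frame` of class `mi_track` with columns `mi`, `n_sites`,
#'   sorted by `mi`.
#' @export
mi_track <- function(mi, n_sites) {
  if (length(mi) != length(n_sites)) stopf("mi and n_sites lengths differ")
  if (anyDuplicated(mi)) stopf("duplicate MI values in track")
  if (any(n_sites < 0)) stopf("n_sites must be non-negative")
  if (length(mi) > 0 && sum(n_sites) <= 0) stopf("track has no sites")
  out <- data.frame(mi = as.integer(mi), n_sites = as.numeric(n_sites))
  out <- out[order(out$mi), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mi_track", "data.frame")
  out
}

#' Generate a genome-like MI site track from a normal mixture
#'
#' Site counts over integer MI values follow a discretised mixture of
#' normals (each integer MI gets the mass of the unit interval centred on
#' it), truncated to `mi_range` and sampled multinomially so the total is
#' exactly `n_total`. The default two-component mixture emulates the
#' qualitative shape of a genome MI distribution: a dominant low-MI bulk
#' plus a small high-MI (CpG-like) hump.
#'
#' @param n_total total number of sites (> 0).
#' @param mixture_spec a data.frame (or list of length-3 vectors) with
#'   columns/elements `weight`, `mean_mi`, `sd_mi`; weights must sum to 1.
#' @param mi_range length-2 integer vector, inclusive MI range.
#' @param seed optional integer seed.
#' @return an [mi_track()] (zero-count MI values are dropped).
#' @examples
#' tr <- make_mi_track(1e5, seed = 1)
#' sum(tr$n_sites)
#' @export
make_mi_track <- function(n_total,
                          mixture_spec = data.frame(
                            weight = c(0.95, 0.05),
                            mean_mi = c(-15, 85),
                            sd_mi = c(10, 10)),
                          mi_range = c(-40L, 120L),
                          seed = NULL) {
  if (is.list(mixture_spec) && !is.data.frame(mixture_spec)) {
    mixture_spec <- do.call(rbind, lapply(mixture_spec, function(cmp) {
      data.frame(weight = cmp[[1]], mean_mi = cmp[[2]], sd_mi = cmp[[3]])
    }))
  }
  if (NROW(mixture_spec) == 0) stopf("mixture_spec is empty")
  if (!all(c("weight", "mean_mi", "sd_mi") %in% names(mixture_spec))) {
    stopf("mixture_spec needs columns weight, mean_mi, sd_mi")
  }
  if (abs(sum(mixture_spec$weight) - 1) > 1e-8) {
    stopf("mixture weights must sum to 1 (got %g)", sum(mixture_spec$weight))
  }
  if (n_total <= 0) stopf("n_total must be positive")
  if (length(mi_range) != 2L || mi_range[2] < mi_range[1]) {
    stopf("mi_range must be a non-empty integer interval")
  }
  grid <- seq.int(mi_range[1], mi_range[2])
  prob <- rowSums(mapply(
    function(w, m, s) w * (stats::pnorm(grid + 0.5, m, s) -
                           stats::pnorm(grid - 0.5, m, s)),
    mixture_spec$weight, mixture_spec$mean_mi, mixture_spec$sd_mi
  ))
  if (sum(prob) <= 0) stopf("mixture places no mass on mi_range")
  counts <- with_seed(seed, as.vector(stats::rmultinom(1, n_total, prob)))
  keep <- counts > 0
  mi_track(grid[keep], counts[keep])
}

#' Construct a true per-site mutation-rate model
#'
#' The generating model behind synthetic DNMs: the mean rate at MI value
#' `x` is `log_base^(intercept + slope * x)`, and each individual site's
#' rate is that mean times a mean-one lognormal factor with variance
#' `cryptic_variance` — rate variation at single-site resolution that no
#' MI-level summary can see directly.
#'
#' @param intercept,slope coefficients of the log-linear rate model.
#' @param log_base base of the logarithm (default 10).
#' @param cryptic_variance variance of the mean-one per-site factor (>= 0).
#' @return a list of class `true_rate_model`.
#' @export
true_rate_model <- function(intercept, slope, log_base = 10,
                            cryptic_variance = 0) {
  check_log_base(log_base)
  if (cryptic_variance < 0) stopf("cryptic_variance must be >= 0")
  structure(
    list(intercept = intercept, slope = slope, log_base = log_base,
         cryptic_variance = cryptic_variance),
    class = "true_rate_model")
}

#' Sample a de novo mutation dataset from an MI track
#'
#' Per-site counts are Poisson with mean `c * rate(mi) * factor`, where
#' `rate(mi)` comes from the model, `factor` is a per-site mean-one
#' lognormal draw with variance `model$cryptic_variance`, and the scale `c`
#' is set so the expected total equals `n_dnm_target`. An optional
#' MI-dependent retention probability thins the records afterwards,
#' emulating systematic under-reporting of mutations from parts of the
#' genome (e.g. the more mutable ones).
#'
#' @param track an [mi_track()].
#' @param model a [true_rate_model()].
#' @param n_dnm_target expected total number of DNMs before thinning.
#' @param reporting_bias `NULL`, or `function(mi)` returning a retention
#'   probability in \[0, 1\] for each MI value.
#' @param seed optional integer seed.
#' @param study study label stored with every record.
#' @return a `data.frame` of class `dnm_dataset` with columns
#'   `chrom`, `pos`, `mi`, `study`; `pos` indexes sites 1..N within the
#'   track (positions are opaque labels — only MI matters downstream).
#' @examples
#' tr <- make_mi_track(1e4, seed = 1)
#' dn <- sample_dnms(tr, true_rate_model(-1.3, 0.01), 500, seed = 2)
#' nrow(dn)
#' @export
sample_dnms <- function(track, model, n_dnm_target, reporting_bias = NULL,
                        seed = NULL, study = "synthetic") {
  stopifnot(inherits(track, "mi_track"), inherits(model, "true_rate_model"))
  if (n_dnm_target <= 0) stopf("n_dnm_target must be positive")
  rate <- model$log_base^(model$intercept + model$slope * track$mi)
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stopf("rate model must be positive and finite over the track")
  }
  scale <- n_dnm_target / sum(track$n_sites * rate)
  site_mi <- rep.int(track$mi, track$n_sites)
  n_sites_total <- length(site_mi)
  with_seed(seed, {
    lambda <- scale * model$log_base^(model$intercept + model$slope * site_mi)
    if (model$cryptic_variance > 0) {
      lambda <- lambda * rlnorm_mean_one(n_sites_total,
                                         model$cryptic_variance)
    }
    counts <- stats::rpois(n_sites_total, lambda)
    hit <- which(counts > 0L)
    idx <- rep.int(hit, counts[hit])
    mi <- site_mi[idx]
    if (!is.null(reporting_bias)) {
      p <- reporting_bias(mi)
      if (any(p < 0 | p > 1 | !is.finite(p))) {
        stopf("reporting_bias must return probabilities in [0, 1]")
      }
      keep <- stats::runif(length(idx)) < p
      idx <- idx[keep]
      mi <- mi[keep]
    }
    out <- data.frame(chrom = rep("chr1", length(idx)), pos = idx, mi = mi,
                      study = rep(study, length(idx)),
                      stringsAsFactors = FALSE)
    class(out) <- c("dnm_dataset", "data.frame")
    out
  })
}

#' Sample a two-species coincident-SNP table under gamma rate heterogeneity
#'
#' Each site receives a rate multiplier \eqn{\gamma} from a mean-one gamma
#' distribution with the given shape, and is marked coincident (a SNP in
#' both species) with probability
#' \deqn{u_a u_b \left(e^{-v\gamma}\gamma^2 + (1 - e^{-2v\gamma})\right),}
#' the per-site coincidence kernel of the gamma-rate theory (see
#' [mutation_kernel()]). Sampling the kernel directly — rather than
#' simulating full mutation histories — is the Monte-Carlo realisation of
#' the model being validated. `snp_a`/`snp_b` are both `TRUE` exactly at
#' coincident sites; single-species-only SNPs are not modelled because only
#' coincidence enters any downstream computation.
#'
#' @param n_sites number of sites.
#' @param shape gamma shape (> 0); the mean is fixed at 1 so the rate
#'   parameter equals the shape and the variance is `1/shape`.
#' @param v divergence per site between the species, in (0, 1).
#' @param u_a,u_b SNP densities per site in the two species (in \[0, 1\],
#'   small enough that the per-site probability stays <= 1).
#' @param seed optional integer seed.
#' @param is_cpg logical flag stored with every site (default `FALSE`).
#' @return a `data.frame` of class `snp_table` with columns `site_id`,
#'   `is_cpg`, `snp_a`, `snp_b`, `gamma_true`, `mi` (`NA`; synthetic sites
#'   carry no MI).
#' @export
sample_coincident_snps <- function(n_sites, shape, v, u_a, u_b,
                                   seed = NULL, is_cpg = FALSE) {
  if (n_sites <= 0) stopf("n_sites must be positive")
  if (shape <= 0) stopf("shape must be > 0")
  if (v <= 0 || v >= 1) stopf("divergence v must lie in (0, 1)")
  if (u_a < 0 || u_b < 0 || u_a > 1 || u_b > 1) {
    stopf("u_a and u_b must lie in [0, 1]")
  }
  with_seed(seed, {
    gamma_true <- stats::rgamma(n_sites, shape = shape, rate = shape)
    p <- u_a * u_b * mutation_kernel(gamma_true, v)
    if (any(p > 1)) stopf("u_a * u_b too large: coincidence probability > 1")
    coincident <- stats::runif(n_sites) < p
    out <- data.frame(site_id = seq_len(n_sites),
                      is_cpg = rep(isTRUE(is_cpg), n_sites),
                      snp_a = coincident, snp_b = coincident,
                      gamma_true = gamma_true, mi = NA_integer_)
    class(out) <- c("snp_table", "data.frame")
    out
  })
}

#' Empirical coincident-SNP excess of a table
#'
#' The observed coincident fraction divided by the uniform-rate expectation
#' `u_a * u_b * kernel(1, v)` — the Monte-Carlo counterpart of
#' [excess_ratio()], suitable as input to [fold_from_excess()].
#'
#' @param snps an `snp_table` (only `snp_a`, `snp_b` are used).
#' @param u_a,u_b the SNP densities the table was generated with.
#' @param v divergence per site.
#' @return the empirical excess ratio (1 = no rate heterogeneity signal).
#' @export
empirical_excess <- function(snps, u_a, u_b, v) {
  stopifnot(all(c("snp_a", "snp_b") %in% names(snps)))
  if (u_a <= 0 || u_b <= 0) stopf("u_a and u_b must be positive")
  mean(snps$snp_a & snps$snp_b) / (u_a * u_b * mutation_kernel(1, v))
}
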