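---
title: "Methods: bin-averaged mutation-rate models and coincident-SNP theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-averaged mutation-rate models and coincident-SNP theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `cryptvar`, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish about real data.

## The bin-averaging problem

A mutability-index (MI) model assigns every genomic site a score
predicting its mutation rate. Its fit is usually assessed by counting, for
each MI value, the number of genomic sites `n` and the number of de novo
mutations (DNMs) `d` observed at them, and correlating `log(z)` with MI,
where `z = d/n`. The difficulty is that `n` is huge: per-site rate
variance that the model fails to capture shrinks by a factor of `n` when
sites are averaged into a per-MI rate, so even enormous unexplained
variance is nearly invisible in the binned correlation.

`cryptvar` makes that argument quantitative:

1. `bin_by_mi()` bins DNMs into MI intervals of width 10 and removes bins
   with 5 or fewer DNMs (too few events for a stable rate). `mi_mid` is
   the site-count-weighted mean MI of the bin.
2. `fit_loglinear()` fits `log(z) = a + b·MI` by weighted least squares.
3. `predict_expected_counts()` converts the fit into per-bin expected
   counts `Z = n·base^(a + b·mi_mid)`.
4. `simulate_counts()` multiplies `Z` by a mean-one lognormal factor with
   variance `ϒ/n` — `ϒ` being the hypothesised unexplained per-site
   variance — and draws a Poisson count. The `ϒ/n` rule comes from the
   fact that the mean of `n` independent mean-one lognormal variates of
   variance `ϒ` is itself approximately lognormal with variance `ϒ/n`;
   this approximation is verified directly in the test suite (relative
   error < 10% at `n = 100` over 10^4 replicates).
5. `run_table1()` repeats this 1000 times, dropping any replicate in which
   a bin draws zero DNMs (its log rate is undefined), and reports the
   proportion of kept replicates whose correlation strictly exceeds the
   observed one. `upsilon_sweep()` does this over a grid of `ϒ`.

The diagnostic output is the sweep: if the proportion stays flat over many
orders of magnitude of `ϒ`, the binned correlation simply cannot detect
that much unexplained variance. A mean-one factor with variance `ϒ` has
coefficient of variation `sqrt(ϒ)` (`cv_of_lognormal()`), so flatness up
to `ϒ = 10^4`–`10^5` means per-site rates could vary a hundredfold around
the model's prediction without leaving a trace.

### Assumptions and parameter defaults

* **Weighting.** Bins are weighted by their DNM count `d` by default:
  under Poisson counts the delta method gives `Var[log z] ≈ 1/d`, so this
  is inverse-variance weighting. An equal-weight mode exists for
  sensitivity analyses; with equal weights the fit reduces exactly to
  ordinary least squares (tested to 1e-10).
* **Log base.** Default 10; natural log available. The Pearson
  correlation is invariant to the choice, and every downstream prediction
  reads the base from the fit object, so the choice only rescales slopes.
* **Correlation.** Computed on the binned points (as such data are
  plotted), unweighted, never per-site.
* **Bootstrap.** `run_table1()` refits the regression on a resample of
  the bins (the regression's data points) in each replicate by default,
  propagating uncertainty in the rate-MI relationship; replicates with
  fewer than three distinct MI values are redrawn. A flag disables this
  for variance decomposition.
* **Ties and degenerate inputs.** `proportion_greater` uses a strict
  `>` (ties, a measure-zero event, count as not greater). A constant
  response yields a flagged degenerate fit with slope 0 and `r` reported
  as 0. An exactly collinear input has zero residual variance, so the
  quadratic term's t-test is numerical noise; `fit_quadratic()` reports
  `quad_p = 1` when the quadratic coefficient vanishes there.

## The coincident-SNP theory

Sites carrying a SNP in both of two species at the same position are
evidence of per-site rate variation that has persisted since their
divergence. With per-site rate multipliers `γ` drawn from a mean-one gamma
distribution `D(γ)` with shape `α` (variance `1/α`), and divergence `v`
substitutions per site between the species, the probability that a site
shows a coincident SNP is proportional to the expectation of the kernel

```
k(γ, v) = e^{-vγ} γ² + (1 - e^{-2vγ})
```

(`mutation_kernel()`). The `γ²` term is both lineages mutating
independently; its `e^{-vγ}` damping encodes hypermutable sites destroying
themselves — once a site substitutes, the polymorphism cannot be observed
at the orthologous position; the second term is sharing through ancestral
polymorphism. The SNP-density prefactor `u_a·u_b` cancels from every
ratio the package uses and is carried only in the Monte-Carlo generator.

The pipeline is:

* `excess_ratio(model)` — `E[k]/k(1, v)`: the inflation of the
  coincident-SNP probability relative to a uniform-rate genome. This is
  equated to the observed context-corrected excess (e.g. 1.16 for a "16%
  excess"): after context correction, the remaining excess is exactly the
  inflation attributable to cryptic rate variation, which is the only
  reading under which the observed excess determines `α` by itself.
* `fit_gamma_shape(excess, v)` — inverts that relation for `α`.
* `mean_fold_q(model)` — the size-biased mean `Q = E[kγ]/E[k]`, i.e. the
  mean rate of coincident-SNP sites relative to the genomic average.
* `fold_from_excess()` — the composition, with confidence-interval
  endpoints mapped through it (valid because the composition is monotone
  in the excess; monotonicity is asserted on a grid in the tests).

### Numerical choices

* **Quadrature.** Expectations over `D(γ)` use adaptive quadrature after
  the probability transform `γ = Q_gamma(p)`, integrating over
  `p ∈ (0, 1)` at relative tolerance 1e-10. The transform keeps the
  integrand bounded and accurate from strong heterogeneity (`α ~ 1e-3`)
  up to the effectively rate-homogeneous `α = 1e9`, where the density is
  a near-point mass at 1 that untransformed quadrature would miss
  entirely. The tests cross-check the integrals against closed-form gamma
  moments (`E[γ^k e^{-cγ}] = α^α Γ(α+k) / (Γ(α) (α+c)^{α+k})`) and
  against Monte-Carlo means over 10^7 draws.
* **Shape inversion.** At finite `v`, `excess_ratio` is *not* monotone in
  `α`: the self-destruction factor caps it, so it rises from small values
  at extreme heterogeneity to a finite peak and then decreases towards 1.
  `fit_gamma_shape()` therefore root-finds on the decreasing branch: if
  the ratio at the lower bracket (`α = 1e-3`) already exceeds the target
  it brackets directly, otherwise it first locates the peak over
  log-shape and starts there. An excess at or above the peak is reported
  as unattainable. Root-finding is on `log α` with a tolerance that keeps
  the round trip `excess_ratio(fit_gamma_shape(x, v), v) = x` accurate to
  1e-8.
* **Divergences.** Defaults are 0.0092 per site for non-CpG and 0.092 for
  CpG comparisons (CpG sites diverge roughly tenfold faster due to
  methylation-driven deamination); both are arguments, not constants.

## The synthetic-data generators

`make_mi_track()` draws per-MI site counts from a discretised normal
mixture; the default (95% of sites around MI −15, 5% around MI +85, both
sd 10, truncated to [−40, 120]) emulates the qualitative shape of a
genome MI distribution — a dominant low-mutability bulk plus a small
high-mutability, CpG-like hump. The real genome's MI distribution is not
published in a form this package could embed, so the default is
deliberately schematic; its single purpose is to exercise the pipeline
over a realistic dynamic range of per-MI site counts.

`sample_dnms()` draws per-site Poisson counts whose rates are the
log-linear model times an optional mean-one lognormal factor of variance
`ϒ_true` (the unique mean-one lognormal with that variance has log-scale
variance `ln(1+ϒ)` and log-scale mean `−ln(1+ϒ)/2`). The optional
`reporting_bias` retention function emulates MI-dependent
under-reporting, e.g. surveys that miss mutations in the most mutable
regions; the tests confirm such thinning attenuates the fitted slope.

`sample_coincident_snps()` draws `γ` per site and marks the site
coincident with probability `u_a·u_b·k(γ, v)` — a direct Monte-Carlo
realisation of the coincidence kernel, which is the correct object to
sample when the kernel itself is the model under validation. Two
consequences: single-species-only SNPs are not modelled (`snp_a` and
`snp_b` are both true exactly at coincident sites), and the per-site
probability must remain ≤ 1 — with heterogeneous rates the kernel can
reach `~4e^{-2}/v²`, so large SNP densities combined with small
divergence are rejected with an error rather than silently capped. The
bundled analyses use `u = 0.01`, which is safe for all divergences ≥
0.0092.

What passing the synthetic tests shows — and what it does not: the tests
establish that the estimators recover known generating parameters (slope,
shape, fold) under the model's own assumptions, and that the bin-averaging
argument behaves as the theory predicts. They cannot establish that real
DNM surveys have the assumed error structure, that real rates are
gamma-distributed, or what the real genome's MI composition is; published
correlations, slopes and per-dataset proportions depend on those external
inputs and are treated as given numbers where they are needed (e.g. as
inputs to `compare_slopes()`), not as quantities this package could
recompute.

## Problem sizes

The bundled analyses and tests use tracks of 10^5–10^6 sites, DNM sets of
~650–5000 mutations (matching typical published survey sizes), 1000
simulation replicates, and SNP tables of 2×10^6–10^7 sites. One caveat of
scale: with 10^6-site tracks, per-bin site counts are 10^4–10^5, so the
exceedance proportion starts declining around `ϒ ≈ 10^3`; with
genome-scale bins (millions of sites) the decline would begin orders of
magnitude later. The averaging-out acceptance check therefore constructs
bins with 10^7 sites directly, where `ϒ = 10^4` leaves the correlation
distribution statistically indistinguishable from `ϒ = 0`.

## Known limitations

* The fold estimates inherit the gamma assumption; other mean-one mixing
  distributions with the same second moment would give different `Q` at
  the same excess.
* The excess-to-shape inversion treats the observed excess as exact after
  context correction; errors in that correction propagate directly.
* CI propagation maps only the excess CI endpoints; uncertainty in the
  divergence `v` is not propagated (it enters as a fixed constant).
* `Q` is sensitive at the 1% level to how the excess is interpreted
  relative to its baseline; the package fixes one interpretation (the
  uniform-rate kernel at `γ = 1`) and documents it, but alternative
  conventions in the literature can shift the second decimal place.
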