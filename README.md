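# cryptvar

How much of the site-to-site variation in the human germline mutation rate
can a predictive model actually explain? Models that score every genomic
site with a mutability index (MI) are usually judged by correlating the
log of the observed number of de novo mutations (DNMs) per site, `z = d/n`,
against MI — but each MI value aggregates thousands to millions of sites,
so any variance the model misses is averaged away before the correlation is
computed. `cryptvar` provides the two computational procedures needed to
quantify that blind spot:

1. **A bin-averaging simulation framework.** DNMs are binned by MI (bins of
   width 10, bins with ≤ 5 DNMs removed) and a weighted log-linear model
   `log z = a + b·MI` is fitted. Simulated datasets are then generated by
   multiplying each bin's expected count `Z(x) = n·10^(a + b·x)` by a
   mean-one lognormal factor with variance `ϒ/n` — the residue of per-site
   unexplained variance `ϒ` after averaging over `n` sites — and Poisson
   sampling. The output is the proportion of simulated datasets whose
   correlation exceeds the observed one, as a function of `ϒ`.

2. **A gamma-rate theory for coincident SNPs.** Sites polymorphic in both
   humans and chimpanzees ("coincident SNPs") are direct evidence of
   cryptic, context-independent rate variation. Assuming per-site rates
   `γ` follow a mean-one gamma distribution `D(γ)` with shape `α`, the
   probability of a coincident SNP at a site is proportional to

   ```
   ∫ D(γ) (e^{-vγ} γ² + (1 - e^{-2vγ})) dγ
   ```

   where `v` is the between-species divergence per site (0.0092 at non-CpG
   sites, 0.092 at CpG) and the `e^{-vγ}` factor encodes hypermutable
   sites destroying themselves by substitution. Inverting an observed
   context-corrected excess of coincident SNPs for `α` and evaluating the
   size-biased mean

   ```
   Q = ∫ D(γ) k(γ,v) γ dγ / ∫ D(γ) k(γ,v) dγ
   ```

   gives the mean fold-hypermutability of coincident-SNP sites relative to
   the genomic average.

Synthetic-data generators (`make_mi_track()`, `sample_dnms()`,
`sample_coincident_snps()`) emulate the statistical structure of the real
inputs — a genome-like MI distribution, Poisson DNM counts with optional
lognormal cryptic variance and MI-dependent under-reporting, and gamma-rate
SNP coincidence — so every stage of the pipeline is testable without
external downloads.

## Worked example

```r
library(cryptvar)

track <- make_mi_track(2e5, seed = 1)                       # genome-like MI track
dnms  <- sample_dnms(track, true_rate_model(-2.5, 0.01),    # ~650 DNMs at slope 0.01
                     650, seed = 2)
bins  <- bin_by_mi(dnms, track)
fit   <- fit_loglinear(bins)
fit
#> log10(z) = -2.523 + 0.009582 * MI  (se 0.0097, 0.00019), r = 0.992, 11 bins

run_table1(bins, fit, simulation_config(upsilon = 1e5, n_reps = 1000, seed = 3))
#> upsilon = 1e+05: 91/1000 replicates kept, r_obs = 0.9924, P(r_sim > r_obs) = 0.000

fold_from_excess(1.83, 0.0092, excess_ci = c(1.80, 1.86))
#> excess 1.830 at divergence 0.0092 -> gamma shape 1.143
#> fold-hypermutability Q = 2.720 (95% CI 2.657, 2.783)
```

The fit recovers the generating slope (0.0096 ± 0.0002 vs 0.01) with an
excellent binned correlation (r = 0.992). The simulation line shows what
an unexplained per-site variance of 10^5 would do *at this dataset's bin
sizes*: most replicates now produce an empty bin and none beats the
observed correlation. The last call converts an 83% excess of non-CpG
coincident SNPs into the headline estimate: coincident-SNP sites are
~2.7-fold more mutable than average, far above what a ~10-MI-unit shift in
model score predicts (~1.2-fold) — the model misses most cryptic variation
at non-CpG sites.

## Analysis workflow

The `analysis/` scripts run the full study on synthetic data, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R    # MI track, 3 DNM sets, SNP tables
Rscript analysis/02_fit_regression.R   # binned fits, curvature, slope tests
Rscript analysis/03_variance_sweep.R   # exceedance proportion vs upsilon
Rscript analysis/04_coincident_folds.R # fold estimates + end-to-end recovery
```

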