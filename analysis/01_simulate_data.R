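#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a genome-like MI site track, three
# DNM datasets of realistic sizes (one of which suffers MI-dependent
# under-reporting), and two-species coincident-SNP tables for CpG and
# non-CpG site classes. All downstream scripts read only these files.

suppressPackageStartupMessages(library(cryptvar))

cfg <- pipeline_config(seed = 1234)
data_dir <- file.path(cfg$out_dir, "data")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating MI track (1e6 sites, bimodal: low-MI bulk + high-MI hump)")
track <- make_mi_track(1e6, seed = cfg$seed)
write_mi_track(track, file.path(data_dir, "mi_track.tsv"))

# Generating model: log10(rate) = -2.5 + 0.010 * MI, no cryptic variance.
model <- true_rate_model(-2.5, 0.010, log_base = cfg$log_base)

# Three DNM studies mirroring typical published set sizes: a small
# model-building set (~650 DNMs), a pooled set (~1380), and a large set
# (~4930) whose high-MI mutations are under-reported at 50%.
sets <- list(
  michaelson_like = list(n = 650, bias = NULL),
  other_like = list(n = 1380, bias = NULL),
  kong_like = list(n = 4933, bias = function(mi) ifelse(mi < 50, 1, 0.5))
)
for (nm in names(sets)) {
  s <- sets[[nm]]
  dn <- sample_dnms(track, model, s$n, reporting_bias = s$bias,
                    seed = cfg$seed + match(nm, names(sets)), study = nm)
  write_dnm_table(dn, file.path(data_dir, paste0("dnm_", nm, ".tsv")))
  message(sprintf("  %s: %d DNMs%s", nm, nrow(dn),
                  if (is.null(s$bias)) "" else " (high-MI under-reported)"))
}

message("Simulating coincident-SNP tables (gamma rate heterogeneity)")
# Shapes chosen near the values the observed excesses imply: strong
# heterogeneity at non-CpG sites, milder at CpG sites.
snp_non_cpg <- sample_coincident_snps(2e6, shape = 1.14, v = cfg$divergence_non_cpg,
                                      u_a = 0.01, u_b = 0.01,
                                      seed = cfg$seed + 10)
snp_cpg <- sample_coincident_snps(2e6, shape = 4.05, v = cfg$divergence_cpg,
                                  u_a = 0.01, u_b = 0.01,
                                  seed = cfg$seed + 11, is_cpg = TRUE)
write_snp_table(snp_non_cpg, file.path(data_dir, "snp_non_cpg.tsv"))
write_snp_table(snp_cpg, file.path(data_dir, "snp_cpg.tsv"))
message(sprintf("  non-CpG: %d coincident of %d sites; CpG: %d of %d",
                sum(snp_non_cpg$snp_a & snp_non_cpg$snp_b), nrow(snp_non_cpg),
                sum(snp_cpg$snp_a & snp_cpg$snp_b), nrow(snp_cpg)))
message("Inputs written under ", data_dir)
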