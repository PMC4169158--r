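# Tab-separated readers and writers for every table the pipeline consumes
# or produces, with validating errors that name the offending column or
# line. One dialect throughout: TSV with a header row, no quoting, UTF-8.
# Positions are 1-based and treated as opaque labels (only MI matters to
# any computation here).

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df
}

# Convert a character column to integer, reporting the first bad file line
# (header is line 1, so data row i lives on line i + 1).
as_integer_col <- function(x, col, path) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stopf("%s: column '%s' is not an integer at line %d (value '%s')",
          path, col, bad[1] + 1L, x[bad[1]])
  }
  out
}

as_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stopf("%s: column '%s' is not numeric at line %d (value '%s')",
          path, col, bad[1] + 1L, x[bad[1]])
  }
  out
}

as_flag_col <- function(x, col, path) {
  out <- as_integer_col(x, col, path)
  if (any(!out %in% c(0L, 1L), na.rm = TRUE)) {
    stopf("%s: column '%s' must be 0/1", path, col)
  }
  out == 1L
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a DNM table
#'
#' TSV with header columns `chrom`, `pos` (1-based integer), `mi`
#' (integer), and optionally `study`.
#'
#' @param path file path.
#' @return `read_dnm_table()`: a `dnm_dataset` data.frame.
#' @export
read_dnm_table <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "mi"))
  out <- data.frame(
    chrom = df$chrom,
    pos = as_integer_col(df$pos, "pos", path),
    mi = as_integer_col(df$mi, "mi", path),
    study = if ("study" %in% names(df)) df$study else
      rep("unknown", nrow(df)),
    stringsAsFactors = FALSE)
  if (any(out$pos < 1, na.rm = TRUE)) stopf("%s: pos must be >= 1", path)
  class(out) <- c("dnm_dataset", "data.frame")
  out
}

#' @rdname read_dnm_table
#' @param dnms a `dnm_dataset`.
#' @export
write_dnm_table <- function(dnms, path) {
  stopifnot(all(c("chrom", "pos", "mi", "study") %in% names(dnms)))
  write_tsv(dnms[, c("chrom", "pos", "mi", "study")], path)
}

#' Read / write an MI site track
#'
#' Two-column TSV (`mi`, `n_sites`); duplicate MI rows are an error. An
#' empty file with a header reads as an empty track.
#'
#' @param path file path.
#' @return `read_mi_track()`: an [mi_track()].
#' @export
read_mi_track <- function(path) {
  df <- read_tsv_checked(path, c("mi", "n_sites"))
  mi <- as_integer_col(df$mi, "mi", path)
  n_sites <- as_numeric_col(df$n_sites, "n_sites", path)
  if (anyDuplicated(mi)) {
    stopf("%s: duplicate MI value %d", path, mi[anyDuplicated(mi)])
  }
  if (length(mi) == 0) {
    out <- data.frame(mi = integer(0), n_sites = numeric(0))
    class(out) <- c("mi_track", "data.frame")
    return(out)
  }
  mi_track(mi, n_sites)
}

#' @rdname read_mi_track
#' @param track an [mi_track()].
#' @export
write_mi_track <- function(track, path) {
  stopifnot(all(c("mi", "n_sites") %in% names(track)))
  write_tsv(track[, c("mi", "n_sites")], path)
}

#' Read / write a two-species SNP table
#'
#' TSV with header columns `site_id`, `is_cpg`, `snp_a`, `snp_b` (flags
#' stored as 0/1) and optionally `gamma_true` (positive rate multiplier,
#' synthetic data only) and `mi`.
#'
#' @param path file path.
#' @return `read_snp_table()`: an `snp_table` data.frame.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_checked(path, c("site_id", "is_cpg", "snp_a", "snp_b"))
  out <- data.frame(
    site_id = as_integer_col(df$site_id, "site_id", path),
    is_cpg = as_flag_col(df$is_cpg, "is_cpg", path),
    snp_a = as_flag_col(df$snp_a, "snp_a", path),
    snp_b = as_flag_col(df$snp_b, "snp_b", path),
    gamma_true = if ("gamma_true" %in% names(df))
      as_numeric_col(df$gamma_true, "gamma_true", path) else
      rep(NA_real_, nrow(df)),
    mi = if ("mi" %in% names(df)) as_integer_col(df$mi, "mi", path) else
      rep(NA_integer_, nrow(df)))
  if (any(out$gamma_true <= 0, na.rm = TRUE)) {
    stopf("%s: gamma_true must be positive", path)
  }
  class(out) <- c("snp_table", "data.frame")
  out
}

#' @rdname read_snp_table
#' @param snps an `snp_table`.
#' @export
write_snp_table <- function(snps, path) {
  stopifnot(all(c("site_id", "is_cpg", "snp_a", "snp_b") %in% names(snps)))
  df <- snps
  for (col in c("is_cpg", "snp_a", "snp_b")) df[[col]] <- as.integer(df[[col]])
  keep <- intersect(c("site_id", "is_cpg", "snp_a", "snp_b", "gamma_true",
                      "mi"), names(df))
  write_tsv(df[, keep], path)
}

#' Read / write an MI bin table
#'
#' TSV with header columns `mi_mid`, `n`, `d`, `z`.
#'
#' @param path file path.
#' @return `read_bins()`: an `mi_bins` data.frame.
#' @export
read_bins <- function(path) {
  df <- read_tsv_checked(path, c("mi_mid", "n", "d", "z"))
  out <- data.frame(mi_mid = as_numeric_col(df$mi_mid, "mi_mid", path),
                    n = as_numeric_col(df$n, "n", path),
                    d = as_integer_col(df$d, "d", path),
                    z = as_numeric_col(df$z, "z", path))
  class(out) <- c("mi_bins", "data.frame")
  out
}

#' @rdname read_bins
#' @param bins an `mi_bins` table.
#' @export
write_bins <- function(bins, path) {
  stopifnot(all(c("mi_mid", "n", "d", "z") %in% names(bins)))
  write_tsv(as.data.frame(bins)[, c("mi_mid", "n", "d", "z")], path)
}

#' Serialise / load a regression fit as a flat key-value text block
#'
#' One `key<TAB>value` pair per line, full double precision; `NULL`
#' quadratic fields are omitted and restored as `NULL`.
#'
#' @param path file path.
#' @return `read_fit()`: an `mi_fit`.
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(kv) != 2)) stopf("%s: malformed key-value line", path)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  need <- c("intercept", "slope", "se_intercept", "se_slope", "r",
            "log_base", "weighting", "n_bins", "degenerate")
  missing <- setdiff(need, names(vals))
  if (length(missing) > 0) {
    stopf("%s: missing fit field(s): %s", path,
          paste(missing, collapse = ", "))
  }
  num <- function(k) as.numeric(vals[[k]])
  structure(
    list(intercept = num("intercept"), slope = num("slope"),
         se_intercept = num("se_intercept"), se_slope = num("se_slope"),
         r = num("r"), log_base = num("log_base"),
         weighting = vals[["weighting"]], n_bins = as.integer(vals[["n_bins"]]),
         degenerate = as.logical(vals[["degenerate"]]),
         quad_coeff = if ("quad_coeff" %in% names(vals)) num("quad_coeff"),
         quad_p = if ("quad_p" %in% names(vals)) num("quad_p")),
    class = "mi_fit")
}

#' @rdname read_fit
#' @param fit an `mi_fit`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mi_fit"))
  fmt <- function(x) format(x, digits = 17)
  lines <- c(
    paste0("intercept\t", fmt(fit$intercept)),
    paste0("slope\t", fmt(fit$slope)),
    paste0("se_intercept\t", fmt(fit$se_intercept)),
    paste0("se_slope\t", fmt(fit$se_slope)),
    paste0("r\t", fmt(fit$r)),
    paste0("log_base\t", fmt(fit$log_base)),
    paste0("weighting\t", fit$weighting),
    paste0("n_bins\t", fit$n_bins),
    paste0("degenerate\t", fit$degenerate))
  if (!is.null(fit$quad_coeff)) {
    lines <- c(lines, paste0("quad_coeff\t", fmt(fit$quad_coeff)),
               paste0("quad_p\t", fmt(fit$quad_p)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline defaults
#'
#' The shared configuration record: every field documents the default the
#' analyses use throughout (bin width 10, minimum 6 DNMs per retained bin
#' i.e. `min_dnm = 5` with bins of 5 or fewer removed, 1000 simulation
#' replicates, divergences 0.0092 non-CpG / 0.092 CpG, log base 10,
#' DNM-count regression weights).
#'
#' @param seed master seed.
#' @param log_base log base for the rate regression.
#' @param bin_width MI bin width.
#' @param min_dnm drop bins with `d <= min_dnm`.
#' @param weighting regression weighting scheme.
#' @param divergence_cpg,divergence_non_cpg per-site divergences.
#' @param upsilons unexplained-variance sweep values.
#' @param n_reps simulation replicates per upsilon.
#' @param out_dir output directory for analysis scripts.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, log_base = 10, bin_width = 10L,
                            min_dnm = 5L, weighting = "dnm",
                            divergence_cpg = 0.092,
                            divergence_non_cpg = 0.0092,
                            upsilons = c(0, 1e3, 1e4, 1e5, 5e5, 1e6, 2e6,
                                         3e6, 4e6, 5e6),
                            n_reps = 1000L, out_dir = "results") {
  structure(
    list(seed = as.integer(seed), log_base = log_base,
         bin_width = as.integer(bin_width), min_dnm = as.integer(min_dnm),
         weighting = weighting, divergence_cpg = divergence_cpg,
         divergence_non_cpg = divergence_non_cpg, upsilons = upsilons,
         n_reps = as.integer(n_reps), out_dir = out_dir),
    class = "pipeline_config")
}
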