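#' Simulation configuration for a synthetic two-arm AML cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate the
#' design of a randomized two-arm induction trial profiled on three
#' methylation platforms: an enrichment-sequencing count layer over a fixed
#' 500-bp genomic grid, a single-CpG array layer (beta values), and a
#' mass-spectrometry CpG-unit layer with missing values. Response-associated
#' differential methylation is planted into a known set of bins ("truth
#' table") so that recovery by the downstream screen can be measured.
#'
#' @param n_samples_per_arm Samples per treatment arm (STD and EXP). Must be
#'   at least 4 so every arm-by-response cell can hold two samples.
#' @param n_bins Total number of 500-bp genomic bins across all chromosomes.
#' @param bin_size Bin width in bp (fixed grid, 0-based half-open).
#' @param chrom_layout Named numeric vector of chromosome weights; bins are
#'   apportioned proportionally. Must include `chr3`, `chr11` and `chrX` so
#'   the chromosome-exclusion rules of the selection stage are exercised.
#' @param n_planted_dmrs_exp,n_planted_dmrs_std Number of bins carrying a
#'   planted response-linked methylation difference in each arm.
#' @param planted_log2fc Planted log2 fold change between responders and
#'   non-responders at planted bins (default `log2(2.5)`, the effect size the
#'   selection stage screens for).
#' @param nb_dispersion Negative-binomial dispersion of bin counts
#'   (`0` gives the Poisson limit).
#' @param library_size_mean Mean sequencing library size in reads.
#' @param library_size_cv Lognormal coefficient of variation of library sizes.
#' @param n_lowcount_outliers Number of samples per cohort whose library is
#'   forced below 1e6 reads, to exercise the low-count QC flag.
#' @param beta_precision Precision of the Beta distribution generating array
#'   beta values around the underlying methylation level.
#' @param probe_coverage Fraction of candidate regions represented by at
#'   least one array probe (uncovered regions emulate array non-coverage).
#' @param max_probes_per_region Upper bound of the 1..max probes drawn for a
#'   covered region.
#' @param n_null_regions Unplanted regions added to the array/unit layers so
#'   confirmation criteria see both signal and noise.
#' @param unit_noise_sd Gaussian measurement noise of CpG-unit methylation
#'   (truncated to `[0, 1]`).
#' @param missing_rate Missing-completely-at-random rate of unit entries.
#' @param n_high_missing_units Units forced to >20% missingness, to exercise
#'   the unit QC filter.
#' @param response_coefficients Coefficients of the logistic model generating
#'   the response label. The first element is the intercept (default 0.2, so
#'   the complete-response fraction is `plogis(0.2)` = 55%); optional further
#'   elements multiply standard-normal latent covariates.
#' @param exact_response_fraction If `TRUE`, fix the per-arm responder count
#'   at `round(plogis(b0) * n)` instead of drawing it binomially.
#' @param arm_overlap If `TRUE`, half of the STD-arm planted bins coincide
#'   with EXP-arm planted bins (exercises the arm-overlap exclusion rule).
#' @param seed Integer seed; the same configuration and seed reproduce every
#'   generated table exactly.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_samples_per_arm = 8, n_bins = 500, seed = 1)
#' cfg$planted_log2fc
#' @export
sim_config <- function(n_samples_per_arm = 20,
                       n_bins = 20000,
                       bin_size = 500,
                       chrom_layout = c(chr1 = 0.30, chr2 = 0.25, chr7 = 0.20,
                                        chr3 = 0.10, chr11 = 0.10, chrX = 0.05),
                       n_planted_dmrs_exp = 50,
                       n_planted_dmrs_std = 50,
                       planted_log2fc = log2(2.5),
                       nb_dispersion = 0.05,
                       library_size_mean = 5e6,
                       library_size_cv = 0.3,
                       n_lowcount_outliers = 1,
                       beta_precision = 50,
                       probe_coverage = 0.8,
                       max_probes_per_region = 7,
                       n_null_regions = 50,
                       unit_noise_sd = 0.05,
                       missing_rate = 0.1,
                       n_high_missing_units = 0,
                       response_coefficients = c(0.2),
                       exact_response_fraction = FALSE,
                       arm_overlap = FALSE,
                       seed = 1L) {
  stopifnot(
    is.numeric(n_samples_per_arm), length(n_samples_per_arm) == 1,
    n_samples_per_arm == round(n_samples_per_arm),
    is.numeric(n_bins), n_bins >= 1, n_bins == round(n_bins),
    bin_size > 0, bin_size == round(bin_size),
    is.numeric(chrom_layout), !is.null(names(chrom_layout)),
    all(chrom_layout > 0),
    n_planted_dmrs_exp >= 0, n_planted_dmrs_std >= 0,
    is.numeric(planted_log2fc), length(planted_log2fc) == 1,
    nb_dispersion >= 0, library_size_mean > 0, library_size_cv >= 0,
    n_lowcount_outliers >= 0,
    beta_precision > 0,
    probe_coverage >= 0, probe_coverage <= 1,
    max_probes_per_region >= 1,
    n_null_regions >= 0,
    unit_noise_sd >= 0, unit_noise_sd < 0.5,
    missing_rate >= 0, missing_rate <= 1,
    n_high_missing_units >= 0,
    is.numeric(response_coefficients), length(response_coefficients) >= 1,
    is.numeric(seed), length(seed) == 1
  )
  if (n_samples_per_arm < 4) {
    stop("`n_samples_per_arm` must be >= 4 so every arm-by-response cell ",
         "can contain at least 2 samples.", call. = FALSE)
  }
  if (!all(c("chr3", "chr11", "chrX") %in% names(chrom_layout))) {
    stop("`chrom_layout` must include chr3, chr11 and chrX.", call. = FALSE)
  }
  if (n_planted_dmrs_exp + n_planted_dmrs_std > n_bins) {
    stop("More planted DMRs than bins.", call. = FALSE)
  }
  structure(
    list(
      n_samples_per_arm = as.integer(n_samples_per_arm),
      n_bins = as.integer(n_bins),
      bin_size = as.integer(bin_size),
      chrom_layout = chrom_layout / sum(chrom_layout),
      n_planted_dmrs_exp = as.integer(n_planted_dmrs_exp),
      n_planted_dmrs_std = as.integer(n_planted_dmrs_std),
      planted_log2fc = planted_log2fc,
      nb_dispersion = nb_dispersion,
      library_size_mean = library_size_mean,
      library_size_cv = library_size_cv,
      n_lowcount_outliers = as.integer(n_lowcount_outliers),
      beta_precision = beta_precision,
      probe_coverage = probe_coverage,
      max_probes_per_region = as.integer(max_probes_per_region),
      n_null_regions = as.integer(n_null_regions),
      unit_noise_sd = unit_noise_sd,
      missing_rate = missing_rate,
      n_high_missing_units = as.integer(n_high_missing_units),
      response_coefficients = response_coefficients,
      exact_response_fraction = isTRUE(exact_response_fraction),
      arm_overlap = isTRUE(arm_overlap),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  samples/arm:", x$n_samples_per_arm,
      " bins:", x$n_bins, "x", x$bin_size, "bp\n")
  cat("  planted DMRs: EXP", x$n_planted_dmrs_exp,
      "/ STD", x$n_planted_dmrs_std,
      sprintf(" (log2FC %.3f)", x$planted_log2fc), "\n")
  cat("  NB dispersion:", x$nb_dispersion,
      " library mean:", format(x$library_size_mean, big.mark = ","), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
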