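# Bin-level QC, normalization and negative-binomial differential testing.
#
# The differential test follows the classic count-based pipeline for
# two-group designs: TMM normalization factors from doubly trimmed
# log-ratios, a common negative-binomial dispersion by conditional maximum
# likelihood on library-size-equalized pseudo-counts, weighted-likelihood
# moderation of per-bin dispersions toward the common value, and a per-bin
# exact test conditioning on the pseudo-count sum.

# ---- internal helpers -------------------------------------------------------

count_matrix <- function(counts) {
  meta_cols <- intersect(c("bin_id", "chrom", "start", "end"),
                         names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), meta_cols), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if ("bin_id" %in% names(counts)) counts$bin_id else NULL
  m
}

bin_meta <- function(counts) {
  meta_cols <- intersect(c("bin_id", "chrom", "start", "end"),
                         names(counts))
  counts[, meta_cols, drop = FALSE]
}

#' Filter uninformative genomic bins
#'
#' Retains a bin iff its count is nonzero in at least two samples, i.e.
#' removes all bins with no reads across all or all but one sample. The
#' rule is idempotent.
#'
#' @param counts Wide count tibble (`bin_id`, `chrom`, `start`, `end`, then
#'   one column per sample).
#' @return The filtered tibble, with attributes `n_total` and `n_retained`.
#' @examples
#' x <- tibble::tibble(bin_id = c("b1", "b2"), chrom = "chr1",
#'                     start = c(0L, 500L), end = c(500L, 1000L),
#'                     s1 = c(0L, 3L), s2 = c(0L, 0L), s3 = c(1L, 4L))
#' filter_uninformative_bins(x)  # b1 is nonzero in only one sample
#' @export
filter_uninformative_bins <- function(counts) {
  m <- count_matrix(counts)
  if (nrow(m) == 0 || ncol(m) == 0) {
    stop("empty count matrix", call. = FALSE)
  }
  keep <- rowSums(m > 0) >= 2
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_total") <- nrow(m)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Flag low-count samples
#'
#' Flags samples whose total read count falls strictly below `threshold`
#' (default 1e6 reads); flagged samples are meant to be dropped before
#' differential testing.
#'
#' @param counts Wide count tibble.
#' @param threshold Read-count threshold (strict `<`).
#' @return Tibble with `sample_id`, `total_reads`, `flagged`.
#' @export
flag_lowcount_samples <- function(counts, threshold = 1e6) {
  stopifnot(threshold > 0)
  m <- count_matrix(counts)
  tot <- colSums(m)
  tibble::tibble(sample_id = colnames(m), total_reads = unname(tot),
                 flagged = unname(tot < threshold))
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / ((bin_length / 1000) * (library_size / 1e6))`.
#'
#' @param counts Wide count tibble with `start`/`end` columns giving bin
#'   length.
#' @param library_sizes Optional named per-sample library sizes; defaults to
#'   column sums. All must be positive.
#' @return Tibble of the same shape with counts replaced by RPKM values.
#' @examples
#' x <- tibble::tibble(bin_id = "b1", chrom = "chr1", start = 0L, end = 500L,
#'                     s1 = 10L)
#' compute_rpkm(x, library_sizes = c(s1 = 1e6))$s1  # 20
#' @export
compute_rpkm <- function(counts, library_sizes = NULL) {
  m <- count_matrix(counts)
  bm <- bin_meta(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  library_sizes <- library_sizes[colnames(m)]
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop("library sizes must be positive for all samples", call. = FALSE)
  }
  len_kb <- (counts$end - counts$start) / 1000
  r <- sweep(m / len_kb, 2, library_sizes / 1e6, "/")
  dplyr::bind_cols(bm, tibble::as_tibble(r))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1 and mapped back
#' to the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# ---- TMM normalization ------------------------------------------------------

# Trimmed mean of M-values factor of column `i` against reference column
# `ref`, with 30% trimming on log-ratios and 5% on average log-intensities;
# bins with a zero in either sample are excluded.
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sumtrim = 0.05, min_bins = 50) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  # trimmed estimation is meaningless on a handful of bins; fall back to
  # library-size-only normalization there
  if (length(obs) < min_bins) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m)) return(1)
  lo_m <- quantile(m, logratio_trim); hi_m <- quantile(m, 1 - logratio_trim)
  lo_a <- quantile(a, sumtrim); hi_a <- quantile(a, 1 - sumtrim)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors for a count matrix. The
#' reference sample is the one whose upper-quartile count fraction is
#' closest to the cohort mean; factors are normalized to have geometric
#' mean 1.
#'
#' @param m Numeric count matrix (bins x samples).
#' @param logratio_trim Two-sided trim fraction on log-ratios (default 0.3).
#' @param sumtrim Two-sided trim fraction on average log-intensity
#'   (default 0.05).
#' @return Named vector of normalization factors.
#' @export
tmm_factors <- function(m, logratio_trim = 0.3, sumtrim = 0.05) {
  lib <- colSums(m)
  uq <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(i) {
    if (i == ref) 1 else
      tmm_pair(m[, i], m[, ref], lib[i], lib[ref], logratio_trim, sumtrim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

# ---- dispersion estimation --------------------------------------------------

# Conditional log-likelihood of dispersion `phi` for one group of
# library-equalized pseudo-counts (rows = bins), summed per bin.
group_cll <- function(y, phi) {
  n <- ncol(y)
  z <- rowSums(y)
  const <- lgamma(z + 1) - rowSums(lgamma(y + 1))
  if (phi <= 1e-10) {
    # Poisson limit of the negative-binomial conditional likelihood
    return(const - z * log(n))
  }
  r <- 1 / phi
  const + rowSums(lgamma(y + r)) + lgamma(n * r) -
    lgamma(z + n * r) - n * lgamma(r)
}

cll_total <- function(groups, phi) {
  sum(vapply(groups, function(y) sum(group_cll(y, phi)), numeric(1)))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Maximizes, over a single dispersion shared by all bins, the negative
#' binomial likelihood conditional on each bin's per-group total, computed
#' on pseudo-counts scaled to a common library size.
#'
#' @param pseudo Pseudo-count matrix (bins x samples) at equalized library
#'   sizes.
#' @param group Two-level factor over the columns.
#' @return The common dispersion (a scalar >= 0).
#' @export
estimate_common_dispersion <- function(pseudo, group) {
  groups <- lapply(split(seq_along(group), group),
                   function(j) pseudo[, j, drop = FALSE])
  opt <- stats::optimize(function(lphi) cll_total(groups, exp(lphi)),
                         interval = log(c(1e-6, 5)), maximum = TRUE)
  phi <- exp(opt$maximum)
  # collapse to the Poisson boundary when the optimum sits at the edge
  if (phi <= 1.5e-6 ||
      cll_total(groups, 0) >= opt$objective) 0 else phi
}

# Weighted-likelihood moderated per-bin dispersions: each bin maximizes its
# own conditional likelihood plus `prior_n` pseudo-bins of the cohort-average
# likelihood, over a fixed grid around the common value.
moderate_dispersions <- function(pseudo, group, common, prior_n = 10,
                                 grid_length = 21, grid_range = c(-6, 6)) {
  if (common == 0) return(rep(0, nrow(pseudo)))
  groups <- lapply(split(seq_along(group), group),
                   function(j) pseudo[, j, drop = FALSE])
  grid <- common * 2^seq(grid_range[1], grid_range[2],
                         length.out = grid_length)
  ll <- vapply(grid, function(phi) {
    Reduce(`+`, lapply(groups, group_cll, phi = phi))
  }, numeric(nrow(pseudo)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  score <- ll + prior_n * matrix(colMeans(ll), nrow = nrow(ll),
                                 ncol = length(grid), byrow = TRUE)
  grid[max.col(score, ties.method = "first")]
}

# ---- exact test -------------------------------------------------------------

# Two-sided exact test for one bin: condition on the rounded pseudo-count
# total z = z1 + z2 and sum the probabilities of all splits no more likely
# than the observed one ("double tail"). At phi = 0 this is the conditional
# binomial (Poisson) test.
exact_test_bin <- function(z1, z2, n1, n2, phi) {
  z1 <- round(z1); z2 <- round(z2)
  z <- z1 + z2
  if (z == 0) return(1)
  y <- 0:z
  if (phi <= 1e-10) {
    pr <- stats::dbinom(y, z, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- z / (n1 + n2)
    pr <- stats::dnbinom(y, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(z - y, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  pr <- pr - max(pr)
  p_obs <- pr[z1 + 1]
  # include near-ties within relative 1e-7, the convention of exact
  # binomial double-tail tests
  min(1, sum(exp(pr[pr <= p_obs + 1e-7])) / sum(exp(pr)))
}

#' Negative-binomial exact test for differential methylation
#'
#' Two-group differential test over genomic bins: TMM normalization,
#' conditional-maximum-likelihood common dispersion on library-equalized
#' pseudo-counts, weighted-likelihood moderation of per-bin dispersions
#' toward the common value, and a per-bin two-sided exact test conditioning
#' on the pseudo-count total. P-values are Benjamini-Hochberg adjusted.
#'
#' @param counts Wide count tibble (pre-filtered with
#'   [filter_uninformative_bins()]; an all-zero bin is a contract violation
#'   and raises an error).
#' @param labels Per-sample response labels, `"CR"` (responder, the
#'   reference group of the fold change numerator) or `"RD"`.
#' @param dispersion `"tagwise"` (moderated per-bin, the default),
#'   `"common"`, or a fixed numeric dispersion (`0` = Poisson).
#' @param prior_n Weight (in pseudo-bins) pulling per-bin dispersions toward
#'   the common value.
#' @param library_sizes Optional named library sizes; defaults to column
#'   sums.
#' @return Tibble with one row per bin: bin coordinates, `logFC`
#'   (log2 CR over RD on normalized pseudo-counts), `p_value`, `q_value`,
#'   group mean RPKMs (`rpkm_cr`, `rpkm_rd`) and the `dispersion` used.
#' @examples
#' x <- tibble::tibble(bin_id = "b1", chrom = "chr1", start = 0L, end = 500L,
#'                     a1 = 10L, a2 = 10L, b1 = 40L, b2 = 40L)
#' nb_differential_test(x, c("RD", "RD", "CR", "CR"), dispersion = 0,
#'                      library_sizes = c(a1 = 1e6, a2 = 1e6,
#'                                        b1 = 1e6, b2 = 1e6))
#' @export
nb_differential_test <- function(counts, labels,
                                 dispersion = c("tagwise", "common"),
                                 prior_n = 10,
                                 library_sizes = NULL) {
  m <- count_matrix(counts)
  bm <- bin_meta(counts)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) {
    stop("`labels` must have one entry per sample column", call. = FALSE)
  }
  if (!all(labels %in% c("CR", "RD"))) {
    stop("labels must be 'CR' or 'RD'", call. = FALSE)
  }
  if (min(table(labels)) < 2 || length(unique(labels)) < 2) {
    stop("each response group needs at least 2 samples", call. = FALSE)
  }
  if (any(rowSums(m > 0) < 2)) {
    stop("all-zero or single-sample bins reached the test; run ",
         "filter_uninformative_bins() first", call. = FALSE)
  }
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  library_sizes <- library_sizes[colnames(m)]

  f <- tmm_factors(m)
  eff_lib <- library_sizes * f
  common_lib <- exp(mean(log(eff_lib)))
  pseudo <- sweep(m, 2, common_lib / eff_lib, "*")
  group <- factor(labels, levels = c("RD", "CR"))

  if (is.numeric(dispersion)) {
    phi <- rep(dispersion, nrow(m))
    common <- dispersion
  } else {
    dispersion <- match.arg(dispersion)
    common <- estimate_common_dispersion(pseudo, group)
    phi <- if (dispersion == "common") rep(common, nrow(m))
           else moderate_dispersions(pseudo, group, common, prior_n)
  }

  idx_cr <- which(group == "CR"); idx_rd <- which(group == "RD")
  n1 <- length(idx_rd); n2 <- length(idx_cr)
  z_rd <- rowSums(pseudo[, idx_rd, drop = FALSE])
  z_cr <- rowSums(pseudo[, idx_cr, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(i) {
    exact_test_bin(z_rd[i], z_cr[i], n1, n2, phi[i])
  }, numeric(1))

  mean_cr <- z_cr / n2
  mean_rd <- z_rd / n1
  logfc <- ifelse(mean_cr > 0 & mean_rd > 0,
                  log2(mean_cr / mean_rd),
                  log2((mean_cr + 0.125) / (mean_rd + 0.125)))

  rpkm <- count_matrix(compute_rpkm(counts, library_sizes = eff_lib))
  out <- dplyr::bind_cols(
    bm,
    tibble::tibble(
      logFC = unname(logfc),
      p_value = p,
      q_value = adjust_bh(p),
      rpkm_cr = unname(rowMeans(rpkm[, idx_cr, drop = FALSE])),
      rpkm_rd = unname(rowMeans(rpkm[, idx_rd, drop = FALSE])),
      dispersion = unname(phi)
    )
  )
  attr(out, "common_dispersion") <- common
  attr(out, "norm_factors") <- f
  out
}
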