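# Cross-platform confirmation of enrichment-derived DMRs against single-CpG
# array beta values: probe-to-region mapping, beta-to-M transform, and the
# three confirmation criteria (correlation above the cohort median,
# cross-modality direction concordance, group-difference p below 0.2).

#' Map array probes to candidate regions
#'
#' A probe maps to a region iff `start <= pos < end` (0-based half-open on
#' both sides). Regions without any probe are reported as uncovered.
#'
#' @param probes Probe manifest tibble: `probe_id`, `chrom`, `pos`.
#' @param regions Region tibble: `bin_id`, `chrom`, `start`, `end`.
#' @return Tibble with one row per region-probe pair (`probe_id` is `NA`
#'   for uncovered regions) and a per-region `n_probes` count.
#' @export
map_probes_to_regions <- function(probes, regions) {
  hits <- dplyr::inner_join(regions[, c("bin_id", "chrom", "start", "end")],
                            probes[, c("probe_id", "chrom", "pos")],
                            by = "chrom", relationship = "many-to-many")
  hits <- hits[hits$start <= hits$pos & hits$pos < hits$end, , drop = FALSE]
  counts <- dplyr::count(hits, .data$bin_id, name = "n_probes")
  uncovered <- regions[!(regions$bin_id %in% hits$bin_id),
                       c("bin_id", "chrom", "start", "end")]
  if (nrow(uncovered)) {
    uncovered$probe_id <- NA_character_
    uncovered$pos <- NA_integer_
    uncovered$n_probes <- 0L
  }
  out <- dplyr::left_join(hits, counts, by = "bin_id")
  dplyr::bind_rows(out, uncovered)
}

#' Beta to M value transform
#'
#' `M = log2(beta' / (1 - beta'))` with `beta' = clip(beta, eps, 1 - eps)`.
#' Clipping keeps fully (un)methylated probes finite.
#'
#' @param beta Beta values in `[0, 1]`.
#' @param eps Clipping bound (default 1e-3).
#' @return M values.
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Confirm candidate regions against array measurements
#'
#' Per probe, across samples: (i) Spearman correlation between the probe's
#' beta values and the parent region's normalized enrichment counts must
#' exceed the median correlation over all candidate probes of the run;
#' (ii) the sign of the CR-minus-RD mean beta difference must match the sign
#' of the region's enrichment log fold change (cross-modality direction
#' concordance); (iii) the two-sided Mann-Whitney p-value for the CR vs RD
#' beta difference must fall below `alpha` (default 0.2, a deliberately
#' permissive gate for small cohorts). A region is `confirmed_all` when
#' every probe passes all three criteria, `confirmed_partial` when at least
#' one (but not all) does, and `failed` otherwise. A constant beta vector
#' has no defined rank correlation and fails criterion (i) with a
#' diagnostic.
#'
#' @param mapping Probe-region mapping from [map_probes_to_regions()]
#'   (uncovered regions are ignored).
#' @param regions Top-list records carrying `bin_id` and `logFC`.
#' @param rpkm Wide normalized-count tibble covering the mapped bins.
#' @param betas Wide beta tibble (`probe_id` x samples).
#' @param labels Per-sample `"CR"`/`"RD"` labels aligned with the shared
#'   sample columns of `rpkm` and `betas`.
#' @param alpha Significance gate for criterion (iii).
#' @return A `meth_confirmation` list: `$probes` (per-probe rho, p, flags)
#'   and `$regions` (per-region status).
#' @export
confirm_regions <- function(mapping, regions, rpkm, betas, labels,
                            alpha = 0.2) {
  mp <- mapping[!is.na(mapping$probe_id), , drop = FALSE]
  samples <- intersect(setdiff(names(rpkm),
                               c("bin_id", "chrom", "start", "end")),
                       setdiff(names(betas), "probe_id"))
  if (length(samples) < 3) {
    stop("need at least 3 samples with paired measurements", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != length(samples)) {
    stop("`labels` must align with the shared sample columns", call. = FALSE)
  }
  rmat <- as.matrix(rpkm[, samples, drop = FALSE])
  rownames(rmat) <- rpkm$bin_id
  bmat <- as.matrix(betas[, samples, drop = FALSE])
  rownames(bmat) <- betas$probe_id
  is_cr <- labels == "CR"

  res <- purrr::map_dfr(seq_len(nrow(mp)), function(i) {
    b <- bmat[mp$probe_id[i], ]
    r <- rmat[mp$bin_id[i], ]
    lfc <- regions$logFC[match(mp$bin_id[i], regions$bin_id)]
    constant <- stats::sd(b) == 0
    rho <- if (constant) NA_real_ else
      suppressWarnings(stats::cor(b, r, method = "spearman"))
    dbeta <- mean(b[is_cr]) - mean(b[!is_cr])
    concordant <- !is.na(lfc) && sign(dbeta) == sign(lfc) && dbeta != 0
    p <- if (constant) 1 else
      mw_test(b[is_cr], b[!is_cr])
    tibble::tibble(
      probe_id = mp$probe_id[i], bin_id = mp$bin_id[i],
      rho = rho, p_value = p,
      direction_concordant = concordant,
      note = if (constant) "constant beta vector; rho undefined"
             else NA_character_
    )
  })
  med_rho <- stats::median(res$rho, na.rm = TRUE)
  res$rho_above_median <- !is.na(res$rho) & res$rho > med_rho
  res$significant <- res$p_value < alpha
  res$pass <- res$rho_above_median & res$direction_concordant &
    res$significant

  regs <- res |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(n_probes = dplyr::n(), n_pass = sum(.data$pass),
                     .groups = "drop") |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_pass == .data$n_probes ~ "confirmed_all",
      .data$n_pass >= 1 ~ "confirmed_partial",
      TRUE ~ "failed"
    ))
  structure(list(probes = res, regions = regs, median_rho = med_rho,
                 alpha = alpha),
            class = "meth_confirmation")
}

#' @export
print.meth_confirmation <- function(x, ...) {
  tab <- table(factor(x$regions$status,
                      levels = c("confirmed_all", "confirmed_partial",
                                 "failed")))
  cat("<meth_confirmation>\n")
  cat("  probes:", nrow(x$probes),
      sprintf(" (median rho %.3f, alpha %.2g)", x$median_rho, x$alpha), "\n")
  cat(sprintf("  regions: %d confirmed_all, %d confirmed_partial, %d failed\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

# two-sided Mann-Whitney p-value; exact for small tie-free groups, normal
# approximation with tie correction otherwise
mw_test <- function(x, y, exact_max = 12) {
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Plot per-probe confirmation results
#'
#' Spearman correlation of every candidate probe against the cohort median
#' gate, colored by overall pass/fail of the three confirmation criteria.
#'
#' @param object A `meth_confirmation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meth_confirmation <- function(object, ...) {
  df <- object$probes
  df$rho[is.na(df$rho)] <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = -log10(.data$p_value),
                                   colour = .data$pass)) +
    ggplot2::geom_vline(xintercept = object$median_rho,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "Spearman rho (beta vs region RPKM)",
                  y = "-log10 p (CR vs RD)",
                  colour = "passes all criteria",
                  title = "Array confirmation of candidate regions") +
    ggplot2::theme_minimal()
}
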