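# Distillation of per-arm differential results into a ranked top-candidate
# DMR list: effect-size consistency, chromosome exclusions, arm-overlap
# exclusion, ranking, and genomic annotation.

#' Effect-size consistency of a candidate DMR
#'
#' Operationalizes the "at least `fold`-fold difference in a consistent
#' fraction of at least `min_fraction` of samples" rule: every sample of the
#' higher group is compared against `fold` times the center (default median)
#' of the lower group's normalized counts; the consistent fraction is the
#' share of higher-group samples passing. The higher group is taken from the
#' sign of `logfc` (log2 CR over RD) when supplied, otherwise from the group
#' means.
#'
#' A lower-group center of zero with nonzero higher-group values counts as
#' an infinite ratio (passes); both centers zero fails with a diagnostic.
#'
#' @param x_cr,x_rd Normalized counts (e.g. RPKM) of the responder and
#'   non-responder samples at one bin.
#' @param fold Required fold difference (default 2.5).
#' @param min_fraction Required consistent fraction (default 0.5).
#' @param logfc Optional log2 fold change fixing the direction.
#' @param center Summary of the lower group (`median` default, `mean`
#'   configurable).
#' @return One-row tibble: `fraction`, `direction`
#'   (`hyper_in_RD`/`hypo_in_RD`, i.e. which response group is higher),
#'   `pass`, `note`.
#' @examples
#' effect_size_consistency(rep(100, 5), rep(40, 5))   # ratio 2.5: passes
#' effect_size_consistency(rep(80, 5), rep(40, 5))    # ratio 2.0: fails
#' @export
effect_size_consistency <- function(x_cr, x_rd, fold = 2.5,
                                    min_fraction = 0.5, logfc = NULL,
                                    center = stats::median) {
  if (length(x_cr) < 2 || length(x_rd) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  cr_higher <- if (!is.null(logfc)) logfc >= 0 else mean(x_cr) >= mean(x_rd)
  hi <- if (cr_higher) x_cr else x_rd
  lo <- if (cr_higher) x_rd else x_cr
  lo_c <- center(lo)
  note <- NA_character_
  if (lo_c == 0 && all(hi == 0)) {
    frac <- 0
    note <- "all normalized counts zero in both groups"
  } else if (lo_c == 0) {
    frac <- mean(hi > 0) # ratio +Inf wherever the numerator is nonzero
  } else {
    frac <- mean(hi >= fold * lo_c)
  }
  tibble::tibble(
    fraction = frac,
    direction = if (cr_higher) "hypo_in_RD" else "hyper_in_RD",
    pass = is.na(note) && frac >= min_fraction,
    note = note
  )
}

#' Add consistency metrics to a differential result table
#'
#' Vectorized application of [effect_size_consistency()] over all bins of a
#' [nb_differential_test()] result, using a normalized count matrix.
#'
#' @param results Differential result tibble (needs `bin_id`, `logFC`).
#' @param rpkm Wide normalized-count tibble over the same bins and the
#'   tested samples.
#' @param labels Per-sample `"CR"`/`"RD"` labels for the `rpkm` columns.
#' @inheritParams effect_size_consistency
#' @return `results` with `consistent_fraction`, `direction` and
#'   `consistent` columns appended.
#' @export
add_consistency <- function(results, rpkm, labels, fold = 2.5,
                            min_fraction = 0.5, center = stats::median) {
  m <- count_matrix(rpkm)
  m <- m[match(results$bin_id, rpkm$bin_id), , drop = FALSE]
  cr <- m[, labels == "CR", drop = FALSE]
  rd <- m[, labels == "RD", drop = FALSE]
  # vectorized equivalent of effect_size_consistency() over all bins
  cr_higher <- results$logFC >= 0
  # group sizes may differ, so handle the two orientations separately
  frac <- numeric(nrow(m)); bad <- logical(nrow(m))
  for (orient in c(TRUE, FALSE)) {
    rows <- which(cr_higher == orient)
    if (!length(rows)) next
    hi_m <- if (orient) cr[rows, , drop = FALSE] else rd[rows, , drop = FALSE]
    lo_m <- if (orient) rd[rows, , drop = FALSE] else cr[rows, , drop = FALSE]
    lo_c <- apply(lo_m, 1, center)
    zero_lo <- lo_c == 0
    f <- rowMeans(hi_m >= fold * lo_c)
    f[zero_lo] <- rowMeans(hi_m[zero_lo, , drop = FALSE] > 0)
    all_zero <- zero_lo & rowSums(hi_m) == 0
    f[all_zero] <- 0
    frac[rows] <- f
    bad[rows] <- all_zero
  }
  dplyr::bind_cols(results,
                   tibble::tibble(
                     consistent_fraction = frac,
                     direction = ifelse(cr_higher, "hypo_in_RD",
                                        "hyper_in_RD"),
                     consistent = !bad & frac >= min_fraction))
}

overlaps_any <- function(a, b) {
  # row-wise: does interval a overlap any interval of b on the same chrom?
  if (nrow(a) == 0 || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    j <- b$chrom == a$chrom[i]
    any(b$start[j] < a$end[i] & a$start[i] < b$end[j])
  }, logical(1))
}

#' Build per-arm ranked top DMR lists
#'
#' Admits records with `q_value < q_max` that pass the effect-size
#' consistency rule; excludes any record on the configured chromosomes
#' (default chr3, chr11 and the sex chromosomes, which carry
#' karyotype-driven or sex-driven artifacts); excludes, symmetrically, any
#' record whose bin overlaps a significant record of the other arm (such
#' shared regions indicate unspecific or chemotherapy-associated effects
#' rather than arm-specific ones); ranks by q ascending (ties: larger
#' `|logFC|` first, then genomic order) and truncates each arm's list to
#' `k`.
#'
#' @param exp_results,std_results Per-arm differential results with
#'   consistency columns (see [add_consistency()]).
#' @param k Top-list length per arm (default 50).
#' @param q_max FDR threshold (default 0.05).
#' @param exclude_chroms Chromosomes removed before ranking.
#' @return Tibble of admitted records with an `arm` column and `rank` within
#'   arm.
#' @export
build_top_list <- function(exp_results, std_results, k = 50, q_max = 0.05,
                           exclude_chroms = c("chr3", "chr11",
                                              "chrX", "chrY")) {
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  admit <- function(r) {
    r[r$q_value < q_max & r$consistent &
        !(r$chrom %in% exclude_chroms), , drop = FALSE]
  }
  sig_exp <- admit(exp_results)
  sig_std <- admit(std_results)
  keep_exp <- !overlaps_any(sig_exp, sig_std)
  keep_std <- !overlaps_any(sig_std, sig_exp)
  rank_arm <- function(r, arm) {
    r <- dplyr::arrange(r, .data$q_value, dplyr::desc(abs(.data$logFC)),
                        .data$chrom, .data$start)
    r <- utils::head(r, k)
    if (nrow(r)) r$rank <- seq_len(nrow(r))
    r$arm <- rep(arm, nrow(r))
    r
  }
  dplyr::bind_rows(rank_arm(sig_exp[keep_exp, , drop = FALSE], "EXP"),
                   rank_arm(sig_std[keep_std, , drop = FALSE], "STD"))
}

#' Assemble an annotation track
#'
#' @param tss Tibble `chrom`, `pos` of transcription start sites.
#' @param genes Tibble `chrom`, `gene_id`, `start`, `end` of gene bodies.
#' @param exons Tibble `chrom`, `gene_id`, `start`, `end` of exons.
#' @param gc Either a tibble `bin_id`, `gc_fraction`, or a named character
#'   vector of bin sequences from which GC fraction is computed.
#' @return An `annotation_track` list.
#' @export
make_annotation_track <- function(tss, genes, exons, gc = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(tss)),
            all(c("chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "start", "end") %in% names(exons)))
  structure(list(tss = tss, genes = genes, exons = exons, gc = gc),
            class = "annotation_track")
}

gc_fraction_of <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)
  vapply(chars, function(x) mean(x %in% c("G", "C")), numeric(1))
}

#' Annotate DMR records with TSS distance, GC content and genomic class
#'
#' Signed distance runs from the nearest TSS to the bin midpoint (negative
#' = upstream of the TSS). Genomic class precedence is promoter (midpoint
#' within `promoter_window` bp upstream of a TSS) > exon > intron >
#' intergenic. Chromosomes absent from the track yield `NA` annotations
#' rather than errors.
#'
#' @param records Tibble with `bin_id`, `chrom`, `start`, `end`.
#' @param track An [make_annotation_track()] object.
#' @param promoter_window Promoter window upstream of a TSS in bp
#'   (default 2000).
#' @return `records` with `tss_distance`, `gc_fraction`, `genomic_class`
#'   appended.
#' @export
annotate_regions <- function(records, track, promoter_window = 2000) {
  stopifnot(inherits(track, "annotation_track"))
  mid <- (records$start + records$end) / 2
  n <- nrow(records)
  tss_d <- rep(NA_real_, n)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ts <- track$tss[track$tss$chrom == records$chrom[i], ]
    in_exon <- any(track$exons$chrom == records$chrom[i] &
                     track$exons$start <= mid[i] &
                     mid[i] < track$exons$end)
    in_gene <- any(track$genes$chrom == records$chrom[i] &
                     track$genes$start <= mid[i] &
                     mid[i] < track$genes$end)
    if (nrow(ts)) {
      d <- mid[i] - ts$pos
      tss_d[i] <- d[which.min(abs(d))]
      cls[i] <- if (tss_d[i] >= -promoter_window && tss_d[i] < 0) {
        "promoter"
      } else if (in_exon) "exon" else if (in_gene) "intron" else "intergenic"
    } else if (records$chrom[i] %in% track$genes$chrom) {
      cls[i] <- if (in_exon) "exon" else if (in_gene) "intron"
             else "intergenic"
    }
  }
  gcf <- rep(NA_real_, n)
  if (!is.null(track$gc)) {
    if (is.data.frame(track$gc)) {
      gcf <- track$gc$gc_fraction[match(records$bin_id, track$gc$bin_id)]
    } else {
      hit <- match(records$bin_id, names(track$gc))
      gcf[!is.na(hit)] <- gc_fraction_of(track$gc[hit[!is.na(hit)]])
    }
  }
  dplyr::bind_cols(records,
                   tibble::tibble(tss_distance = tss_d, gc_fraction = gcf,
                                  genomic_class = cls))
}
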