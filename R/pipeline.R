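# End-to-end orchestration: QC -> per-arm differential screen -> top-list
# selection -> array confirmation -> unit QC -> signature training,
# refinement and recomposition -> 0.632+ bootstrap evaluation.

#' Pipeline configuration with every stage parameter materialized
#'
#' Collects all thresholds of the analysis in one resolved list (no hidden
#' defaults at run time): the low-count sample threshold, FDR level,
#' fold-change/consistency rule, top-list length, chromosome exclusions,
#' confirmation alpha, unit missingness bound, kNN neighbors, elastic-net
#' and lasso settings, bootstrap replicates, and the root seed from which
#' every stage seed is derived.
#'
#' @param sim A [sim_config()] describing the synthetic cohort (used when
#'   no cohort is supplied to [run_pipeline()]).
#' @param lowcount_threshold Minimum total reads per sample.
#' @param fdr FDR threshold for DMR significance.
#' @param fold,min_fraction Effect-size consistency rule.
#' @param top_k Top-list length per arm.
#' @param exclude_chroms Chromosomes excluded from the top list.
#' @param confirm_alpha Significance gate of the array confirmation.
#' @param max_missing Maximum unit missingness fraction.
#' @param k_neighbors kNN imputation neighbors.
#' @param alpha_enet Elastic-net mixing for the first-pass signature.
#' @param unit_alpha Mann-Whitney level for unit refinement.
#' @param bootstrap_B Bootstrap replicates for the 0.632+ evaluation.
#' @param n_fallback_units When no unit passes refinement (e.g. a null
#'   cohort), the recomposition falls back to this many lowest-p units,
#'   flagged `force_selected`, so the bootstrap stage can still quantify
#'   (and correct) the optimism of a forced signature.
#' @param seed Root seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            lowcount_threshold = 1e6,
                            fdr = 0.05,
                            fold = 2.5,
                            min_fraction = 0.5,
                            top_k = 50,
                            exclude_chroms = c("chr3", "chr11",
                                               "chrX", "chrY"),
                            confirm_alpha = 0.2,
                            max_missing = 0.2,
                            k_neighbors = 5,
                            alpha_enet = 0.5,
                            unit_alpha = 0.05,
                            bootstrap_B = 200,
                            n_fallback_units = 10,
                            seed = 1L) {
  structure(
    list(sim = sim, lowcount_threshold = lowcount_threshold, fdr = fdr,
         fold = fold, min_fraction = min_fraction, top_k = top_k,
         exclude_chroms = exclude_chroms, confirm_alpha = confirm_alpha,
         max_missing = max_missing, k_neighbors = k_neighbors,
         alpha_enet = alpha_enet, unit_alpha = unit_alpha,
         bootstrap_B = bootstrap_B, n_fallback_units = n_fallback_units,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full signature-derivation pipeline
#'
#' Executes, on a (by default synthetic) three-platform cohort: low-count
#' sample QC and uninformative-bin filtering; per-arm CR-vs-RD
#' negative-binomial screening with FDR control; effect-size consistency
#' and top-list selection with chromosome and arm-overlap exclusions;
#' array confirmation of the EXP-arm top list; CpG-unit QC and imputation;
#' first-pass elastic-net training on confirmed-probe M values;
#' arm-specific unit refinement; lasso recomposition on retained units; and
#' a 0.632+ bootstrap evaluation of the recomposed signature (the
#' bootstrap trainer re-runs the full cross-validated lasso in every
#' resample). A second evaluation applies the recomposed model to the STD
#' arm to probe arm specificity.
#'
#' Reruns with an identical configuration are bit-identical: every stage
#' seed derives from the root seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built [simulate_cohort()] object (otherwise
#'   simulated from `config$sim`).
#' @return A `meth_pipeline_result` list with all stage outputs and the
#'   resolved configuration.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
  meta <- cohort$meta

  # --- stage 1: sample QC and bin filtering -------------------------------
  flags <- flag_lowcount_samples(cohort$counts, config$lowcount_threshold)
  keep_samples <- flags$sample_id[!flags$flagged]
  meta <- meta[meta$sample_id %in% keep_samples, , drop = FALSE]
  counts <- cohort$counts[, c("bin_id", "chrom", "start", "end",
                              keep_samples)]
  counts <- filter_uninformative_bins(counts)

  # --- stage 2: per-arm differential screen -------------------------------
  screen_arm <- function(arm) {
    ids <- meta$sample_id[meta$arm == arm]
    sub <- counts[, c("bin_id", "chrom", "start", "end", ids)]
    labels <- meta$response[match(ids, meta$sample_id)]
    res <- nb_differential_test(sub, labels)
    rpkm <- compute_rpkm(sub)
    add_consistency(res, rpkm, labels, fold = config$fold,
                    min_fraction = config$min_fraction)
  }
  res_exp <- screen_arm("EXP")
  res_std <- screen_arm("STD")

  # --- stage 3: top-list selection ----------------------------------------
  top <- build_top_list(res_exp, res_std, k = config$top_k,
                        q_max = config$fdr,
                        exclude_chroms = config$exclude_chroms)
  top_exp <- top[top$arm == "EXP", , drop = FALSE]

  # --- stage 4: array confirmation of the EXP top list --------------------
  exp_ids <- meta$sample_id[meta$arm == "EXP"]
  exp_labels <- meta$response[match(exp_ids, meta$sample_id)]
  confirmation <- NULL
  confirmed_probes <- character(0)
  if (nrow(top_exp) > 0) {
    mapping <- map_probes_to_regions(cohort$probes, top_exp)
    covered <- mapping[!is.na(mapping$probe_id), , drop = FALSE]
    if (nrow(covered) > 0) {
      rpkm_exp <- compute_rpkm(counts[, c("bin_id", "chrom", "start",
                                          "end", exp_ids)])
      confirmation <- confirm_regions(mapping, top_exp, rpkm_exp,
                                      cohort$betas, exp_labels,
                                      alpha = config$confirm_alpha)
      confirmed_probes <- confirmation$probes$probe_id[
        confirmation$probes$pass]
    }
  }

  # --- stage 5: first-pass elastic-net signature on M values --------------
  primary <- NULL
  if (length(confirmed_probes) >= 2) {
    bsub <- cohort$betas[cohort$betas$probe_id %in% confirmed_probes, ]
    mmat <- t(beta_to_m(as.matrix(bsub[, exp_ids, drop = FALSE])))
    colnames(mmat) <- bsub$probe_id
    primary <- fit_penalized_logistic(mmat, exp_labels,
                                      alpha = config$alpha_enet,
                                      seed = stage_seed(config$seed, 11L))
  }

  # --- stage 6: unit QC, refinement and recomposition ---------------------
  qc <- process_unit_matrix(cohort$unit_values, cohort$units,
                            max_missing = config$max_missing,
                            k = config$k_neighbors)
  all_ids <- meta$sample_id
  sel <- select_refinement_units(
    qc$units[, c("unit_id", all_ids)],
    labels = meta$response, arms = meta$arm,
    alpha_level = config$unit_alpha
  )
  retained <- sel$unit_id[sel$retained]
  force_selected <- FALSE
  if (length(retained) == 0 && config$n_fallback_units > 0) {
    force_selected <- TRUE
    retained <- sel$unit_id[order(sel$p_exp)][
      seq_len(min(config$n_fallback_units, nrow(sel)))]
  }
  unit_x <- qc$units[qc$units$unit_id %in% retained,
                     c("unit_id", exp_ids)]
  recomposed <- recompose_signature(unit_x, exp_labels,
                                    unit_manifest = cohort$units,
                                    seed = stage_seed(config$seed, 12L))

  # --- stage 7: 0.632+ bootstrap evaluation -------------------------------
  # the trainer repeats the FULL procedure on every resample: Mann-Whitney
  # unit selection on the in-bag samples (the STD-arm exclusion is fixed:
  # it does not involve the EXP response labels), then the cross-validated
  # lasso. Running selection inside the bootstrap is what removes the
  # selection optimism the 0.632+ estimate is meant to correct.
  xe_all <- t(as.matrix(qc$units[, exp_ids, drop = FALSE]))
  colnames(xe_all) <- qc$units$unit_id
  std_sig_units <- sel$unit_id[sel$sig_std]
  trainer <- make_signature_trainer(
    std_sig_units = std_sig_units,
    alpha_level = config$unit_alpha,
    n_fallback = config$n_fallback_units,
    seed = stage_seed(config$seed, 13L))
  evaluation <- bootstrap_632plus(xe_all, exp_labels, trainer,
                                  B = config$bootstrap_B,
                                  seed = stage_seed(config$seed, 14L))
  xe <- xe_all[, unit_x$unit_id, drop = FALSE]
  pred_exp <- predict_probability(recomposed, xe)
  metrics_exp <- confusion_metrics(pred_exp$call, exp_labels)

  # arm-specificity check: the same signature applied to the STD arm
  std_ids <- meta$sample_id[meta$arm == "STD"]
  std_labels <- meta$response[match(std_ids, meta$sample_id)]
  xs <- t(as.matrix(qc$units[qc$units$unit_id %in% retained,
                             std_ids, drop = FALSE]))
  colnames(xs) <- unit_x$unit_id
  pred_std <- predict_probability(recomposed, xs)
  std_eval <- list(
    metrics = confusion_metrics(pred_std$call, std_labels),
    roc = if (length(unique(std_labels)) == 2) {
      roc_auc(pred_std$probability, std_labels)
    }
  )

  structure(
    list(config = config, cohort = cohort, qc_flags = flags,
         screen = list(EXP = res_exp, STD = res_std),
         top_list = top, confirmation = confirmation,
         primary_signature = primary,
         unit_qc = qc, unit_selection = sel,
         force_selected = force_selected,
         recomposed_signature = recomposed,
         evaluation = evaluation,
         exp_metrics = metrics_exp,
         std_evaluation = std_eval),
    class = "meth_pipeline_result"
  )
}

#' @export
print.meth_pipeline_result <- function(x, ...) {
  cat("<meth_pipeline_result>\n")
  cat("  samples kept:", sum(!x$qc_flags$flagged), "of",
      nrow(x$qc_flags), "\n")
  cat("  significant bins (q<", x$config$fdr, "): EXP ",
      sum(x$screen$EXP$q_value < x$config$fdr), ", STD ",
      sum(x$screen$STD$q_value < x$config$fdr), "\n", sep = "")
  cat("  top list:", sum(x$top_list$arm == "EXP"), "EXP /",
      sum(x$top_list$arm == "STD"), "STD regions\n")
  if (!is.null(x$confirmation)) {
    conf <- mean(x$confirmation$regions$status != "failed")
    cat(sprintf("  confirmed regions: %.0f%%\n", 100 * conf))
  }
  cat("  recomposed signature:", length(x$recomposed_signature$features),
      "unit(s)", if (x$force_selected) "(force-selected fallback)", "\n")
  cat(sprintf("  0.632+ error %.3f | 0.632+ AUC %.3f (B = %d)\n",
              x$evaluation$err632plus, x$evaluation$auc632,
              x$evaluation$B))
  invisible(x)
}

#' Demonstration pipeline configuration
#'
#' A desk-scale configuration for end-to-end runs: 4,000 bins across six
#' chromosomes, 20 samples per arm, 30 planted DMRs per arm at the 2.5-fold
#' effect (or none for a null cohort), 30 additional null regions on the
#' array/unit layers, and 200 bootstrap replicates.
#'
#' @param seed Root seed.
#' @param null If `TRUE`, no differential methylation is planted (a
#'   negative-control cohort).
#' @return A [pipeline_config()].
#' @export
demo_config <- function(seed = 1L, null = FALSE) {
  pipeline_config(
    sim = sim_config(
      n_samples_per_arm = 20, n_bins = 4000,
      n_planted_dmrs_exp = if (null) 0 else 30,
      n_planted_dmrs_std = if (null) 0 else 30,
      n_null_regions = 30, seed = stage_seed(seed, 1L)),
    bootstrap_B = 200, seed = seed)
}

# Full-procedure trainer for bootstrap evaluation: in-bag Mann-Whitney unit
# selection (minus units significant in the STD arm), falling back to the
# lowest-p units when nothing passes, then a cross-validated lasso.
make_signature_trainer <- function(std_sig_units, alpha_level = 0.05,
                                   n_fallback = 10, seed = 1L) {
  function(x, y) {
    p <- apply(x, 2, function(col) mw_test(col[y == "CR"], col[y == "RD"]))
    eligible <- setdiff(colnames(x), std_sig_units)
    keep <- intersect(names(p)[p < alpha_level], eligible)
    if (!length(keep)) {
      pool <- if (length(eligible)) eligible else colnames(x)
      keep <- pool[order(p[pool])][seq_len(min(n_fallback, length(pool)))]
    }
    fit_penalized_logistic(x[, keep, drop = FALSE], y, alpha = 1,
                           nfolds = 5, seed = seed)
  }
}

#' Fraction of recoverable planted DMRs present in the top list
#'
#' Recoverable planted DMRs are the planted bins of the given arm lying on
#' non-excluded chromosomes; recovery is membership in that arm's top list.
#'
#' @param result A `meth_pipeline_result`.
#' @param arm Treatment arm (default `"EXP"`).
#' @return One-row tibble: `n_planted`, `n_recoverable`, `n_recovered`,
#'   `recovery`, plus the top-list false-discovery count `n_unplanted`.
#' @export
planted_recovery <- function(result, arm = "EXP") {
  truth <- result$cohort$truth
  truth <- truth[truth$arm == arm, , drop = FALSE]
  recoverable <- truth$bin_id[!(truth$chrom %in%
                                  result$config$exclude_chroms)]
  top <- result$top_list[result$top_list$arm == arm, , drop = FALSE]
  tibble::tibble(
    n_planted = nrow(truth),
    n_recoverable = length(recoverable),
    n_recovered = sum(recoverable %in% top$bin_id),
    recovery = if (length(recoverable)) {
      sum(recoverable %in% top$bin_id) / length(recoverable)
    } else NA_real_,
    n_top = nrow(top),
    n_unplanted = sum(!(top$bin_id %in% truth$bin_id))
  )
}
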