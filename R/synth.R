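#' @importFrom stats plogis qlogis rbeta rbinom rlnorm rnbinom rnorm rpois
#'   runif median quantile sd
#' @importFrom rlang .data
NULL

# derive a reproducible sub-seed per generator stage, kept inside 32-bit range
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% .Machine$integer.max)
}

#' Simulate cohort metadata for a two-arm induction trial
#'
#' Generates per-sample treatment arm (STD/EXP, randomized, equal sizes),
#' a binary response label (CR = complete response, RD = refractory disease)
#' drawn from a logistic model, and independent clinical covariates: mutation
#' flags for seven recurrently mutated myeloid genes, a karyotype class, age
#' and sex, with prevalences typical of an adult AML trial population.
#'
#' The logistic intercept (first element of `cfg$response_coefficients`)
#' sets the overall CR fraction (default `plogis(0.2)` = 55%); any further
#' coefficients act on independent standard-normal latent covariates, which
#' lets simulations couple response to unobserved heterogeneity.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per sample: `sample_id`, `arm`, `response`,
#'   seven mutation flag columns (`mut_*`), `karyotype`, `age`, `sex`.
#' @examples
#' meta <- simulate_cohort_meta(sim_config(n_samples_per_arm = 10, seed = 1))
#' table(meta$arm, meta$response)
#' @export
simulate_cohort_meta <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- 2L * cfg$n_samples_per_arm
  withr::with_seed(stage_seed(cfg$seed, 1L), {
    arm <- sample(rep(c("STD", "EXP"), each = cfg$n_samples_per_arm))
    b <- cfg$response_coefficients
    eta <- rep(b[1], n)
    if (length(b) > 1) {
      z <- matrix(rnorm(n * (length(b) - 1L)), nrow = n)
      eta <- eta + drop(z %*% b[-1])
    }
    if (cfg$exact_response_fraction) {
      response <- character(n)
      for (a in c("STD", "EXP")) {
        idx <- which(arm == a)
        n_cr <- round(plogis(b[1]) * length(idx))
        response[idx] <- sample(rep(c("CR", "RD"),
                                    c(n_cr, length(idx) - n_cr)))
      }
    } else {
      response <- ifelse(runif(n) < plogis(eta), "CR", "RD")
    }
    prev <- c(TP53 = 0.10, ASXL1 = 0.17, DNMT3A = 0.17, RUNX1 = 0.21,
              IDH1 = 0.08, IDH2 = 0.15, TET2 = 0.10)
    muts <- vapply(prev, function(p) rbinom(n, 1L, p), integer(n))
    colnames(muts) <- paste0("mut_", names(prev))
    karyo <- sample(c("CN", "complex", "t11q23", "del5q", "inv3", "other"),
                    n, replace = TRUE,
                    prob = c(0.42, 0.19, 0.06, 0.04, 0.01, 0.28))
    meta <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      arm = arm,
      response = response
    )
    meta <- dplyr::bind_cols(meta, tibble::as_tibble(muts))
    meta$karyotype <- karyo
    meta$age <- round(pmin(pmax(rnorm(n, 60, 10), 18), 82), 1)
    meta$sex <- sample(c("female", "male"), n, replace = TRUE,
                       prob = c(0.45, 0.55))
    meta
  }) -> meta
  cells <- table(meta$arm, meta$response)
  if (any(dim(cells) < 2) || any(cells < 2)) {
    warning("a treatment-arm by response cell has fewer than 2 samples; ",
            "the cohort is not testable for all contrasts", call. = FALSE)
  }
  meta
}

# fixed 500-bp grid over the configured chromosome layout
build_bins <- function(cfg) {
  n_per <- round(cfg$chrom_layout * cfg$n_bins)
  # distribute rounding remainder onto the largest chromosome
  n_per[which.max(n_per)] <- n_per[which.max(n_per)] +
    (cfg$n_bins - sum(n_per))
  chrom <- rep(names(n_per), n_per)
  idx <- unlist(lapply(n_per, seq_len), use.names = FALSE) - 1L
  tibble::tibble(
    bin_id = sprintf("bin_%06d", seq_len(cfg$n_bins)),
    chrom = chrom,
    start = idx * cfg$bin_size,
    end = (idx + 1L) * cfg$bin_size
  )
}

#' Simulate a bin-level methylation-enrichment count matrix
#'
#' Draws negative-binomial counts over a fixed 500-bp genomic grid:
#' `count ~ NB(mean = lib_s * rho_b * exp(x_s * delta_b), dispersion phi)`,
#' where `rho_b` is a lognormal bin abundance, `lib_s` a lognormal library
#' size, and `delta_b = planted_log2fc * ln 2` at planted bins. The planted
#' shift applies to samples of the designated arm belonging to the planted
#' "hyper" response group, so the expected normalized count ratio between
#' response groups at a planted bin equals `2^planted_log2fc`. Planted bins
#' are drawn uniformly over the whole grid, so some land on chr3/chr11/chrX
#' and exercise the chromosome-exclusion rules downstream.
#'
#' @param cfg A [sim_config()].
#' @param meta Metadata from [simulate_cohort_meta()].
#' @return A list with `counts` (wide tibble: `bin_id`, `chrom`, `start`,
#'   `end`, then one integer column per sample), `truth` (planted-DMR table:
#'   bin, arm, direction, planted log2 fold change) and `library_sizes`
#'   (named vector of target library sizes used as NB means; realized column
#'   sums differ by sampling noise).
#' @export
simulate_bin_counts <- function(cfg, meta) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(meta))
  bins <- build_bins(cfg)
  n <- nrow(meta)
  withr::with_seed(stage_seed(cfg$seed, 2L), {
    sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
    lib <- rlnorm(n, log(cfg$library_size_mean) - sdlog^2 / 2, sdlog)
    if (cfg$n_lowcount_outliers > 0) {
      out <- sample(n, min(cfg$n_lowcount_outliers, n))
      # unsaturated libraries at 4-18% of the cohort mean (well below the
      # 1e6-read QC threshold at the default 5e6-read depth)
      lib[out] <- runif(length(out), 0.04, 0.18) * cfg$library_size_mean
    }
    names(lib) <- meta$sample_id
    rho <- rlnorm(cfg$n_bins, 0, 0.5)
    rho <- rho / sum(rho)

    n_pl <- cfg$n_planted_dmrs_exp + cfg$n_planted_dmrs_std
    truth <- tibble::tibble(bin_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            arm = character(), direction = character(),
                            log2fc = numeric())
    delta <- matrix(0, nrow = cfg$n_bins, ncol = n)
    if (n_pl > 0 && abs(cfg$planted_log2fc) > 0) {
      if (cfg$arm_overlap && cfg$n_planted_dmrs_std > 0) {
        n_shared <- floor(cfg$n_planted_dmrs_std / 2)
        picked <- sample(cfg$n_bins, n_pl - n_shared)
        exp_idx <- picked[seq_len(cfg$n_planted_dmrs_exp)]
        std_idx <- c(exp_idx[seq_len(n_shared)],
                     picked[-seq_len(cfg$n_planted_dmrs_exp)])
      } else {
        picked <- sample(cfg$n_bins, n_pl)
        exp_idx <- picked[seq_len(cfg$n_planted_dmrs_exp)]
        std_idx <- picked[-seq_len(cfg$n_planted_dmrs_exp)]
      }
      plant_one <- function(idx, arm_name) {
        if (!length(idx)) return(NULL)
        dir <- sample(c("hyper_in_RD", "hypo_in_RD"), length(idx),
                      replace = TRUE)
        for (j in seq_along(idx)) {
          hyper_grp <- if (dir[j] == "hyper_in_RD") "RD" else "CR"
          hit <- meta$arm == arm_name & meta$response == hyper_grp
          delta[idx[j], hit] <<- cfg$planted_log2fc * log(2)
        }
        dplyr::bind_cols(bins[idx, ],
                         tibble::tibble(arm = arm_name, direction = dir,
                                        log2fc = cfg$planted_log2fc))
      }
      truth <- dplyr::bind_rows(plant_one(exp_idx, "EXP"),
                                plant_one(std_idx, "STD"))
    }
    mu <- outer(rho, lib) * exp(delta)
    counts <- if (cfg$nb_dispersion == 0) {
      matrix(rpois(length(mu), mu), nrow = cfg$n_bins)
    } else {
      matrix(rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu),
             nrow = cfg$n_bins)
    }
    colnames(counts) <- meta$sample_id
    list(
      counts = dplyr::bind_cols(bins, tibble::as_tibble(counts)),
      truth = truth,
      library_sizes = lib
    )
  })
}

#' Simulate an array probe panel and beta-value matrix for candidate regions
#'
#' Emulates the single-CpG array confirmation layer. Candidate regions are
#' the planted truth-table bins plus `cfg$n_null_regions` unplanted bins. A
#' fraction `probe_coverage` of regions receives 1..`max_probes_per_region`
#' probes at uniform positions inside the bin; the rest are uncovered (no
#' probes), emulating array non-coverage. Each probe's beta value is drawn
#' `Beta(theta * s, (1 - theta) * s)` with precision `s = beta_precision`
#' around the region's underlying methylation level `theta`; at planted
#' regions `theta` is shifted on the logit scale by `planted_log2fc * ln 2`
#' for samples of the planted arm's hyper response group, so array and
#' count layers move in the same direction.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_bin_counts()].
#' @param meta Cohort metadata.
#' @param bins Optional bin table (`bin_id`, `chrom`, `start`, `end`) from
#'   which null regions are drawn; defaults to the grid implied by `cfg`.
#' @return A list with `probes` (probe manifest: `probe_id`, `chrom`, `pos`,
#'   `bin_id`, `planted`), `betas` (wide tibble `probe_id` x samples) and
#'   `theta` (underlying region-by-sample methylation levels used again by
#'   the unit layer).
#' @export
simulate_probe_betas <- function(cfg, truth, meta, bins = NULL) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(meta))
  if (is.null(bins)) bins <- build_bins(cfg)
  withr::with_seed(stage_seed(cfg$seed, 3L), {
    pool <- setdiff(bins$bin_id, truth$bin_id)
    null_ids <- sample(pool, min(cfg$n_null_regions, length(pool)))
    regions <- dplyr::bind_rows(
      dplyr::mutate(truth[, c("bin_id", "chrom", "start", "end",
                              "arm", "direction")], planted = TRUE),
      dplyr::mutate(bins[bins$bin_id %in% null_ids, ],
                    arm = NA_character_, direction = NA_character_,
                    planted = FALSE)
    )
    n_reg <- nrow(regions)
    n <- nrow(meta)
    theta0 <- runif(n_reg, 0.25, 0.75)
    shift <- cfg$planted_log2fc * log(2)
    theta <- matrix(rep(theta0, n), nrow = n_reg)
    for (i in seq_len(n_reg)) {
      if (isTRUE(regions$planted[i])) {
        hyper_grp <- if (regions$direction[i] == "hyper_in_RD") "RD" else "CR"
        hit <- meta$arm == regions$arm[i] & meta$response == hyper_grp
        theta[i, hit] <- plogis(qlogis(theta0[i]) + shift)
      }
    }
    rownames(theta) <- regions$bin_id
    colnames(theta) <- meta$sample_id

    covered <- runif(n_reg) < cfg$probe_coverage
    n_probes <- ifelse(covered,
                       sample(seq_len(cfg$max_probes_per_region), n_reg,
                              replace = TRUE),
                       0L)
    reg_idx <- rep(seq_len(n_reg), n_probes)
    probes <- tibble::tibble(
      probe_id = sprintf("cg%08d", seq_along(reg_idx)),
      chrom = regions$chrom[reg_idx],
      pos = regions$start[reg_idx] +
        floor(runif(length(reg_idx)) * cfg$bin_size),
      bin_id = regions$bin_id[reg_idx],
      planted = regions$planted[reg_idx]
    )
    s <- cfg$beta_precision
    th <- theta[reg_idx, , drop = FALSE]
    betas <- matrix(rbeta(length(th), th * s, (1 - th) * s),
                    nrow = nrow(th))
    colnames(betas) <- meta$sample_id
    list(
      probes = probes,
      betas = dplyr::bind_cols(tibble::tibble(probe_id = probes$probe_id),
                               tibble::as_tibble(betas)),
      theta = theta
    )
  })
}

#' Simulate a CpG-unit methylation matrix with missing values
#'
#' Emulates the mass-spectrometry layer: every assayed probe contributes
#' 1..3 CpG units; a unit's methylation is the region's underlying level
#' plus Gaussian noise `unit_noise_sd`, truncated to `[0, 1]`. Entries are
#' set missing completely at random at `missing_rate`, and
#' `n_high_missing_units` units are forced above 20% missingness so the
#' downstream QC filter has something to remove.
#'
#' @param cfg A [sim_config()].
#' @param probe_panel Output of [simulate_probe_betas()].
#' @param meta Cohort metadata.
#' @return A list with `units` (unit manifest: `unit_id`, `probe_id`,
#'   `bin_id`, `n_cpgs`) and `values` (wide tibble `unit_id` x samples,
#'   `NA` = missing).
#' @export
simulate_unit_table <- function(cfg, probe_panel, meta) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(meta))
  probes <- probe_panel$probes
  theta <- probe_panel$theta
  withr::with_seed(stage_seed(cfg$seed, 4L), {
    n_units <- sample(1:3, nrow(probes), replace = TRUE)
    probe_idx <- rep(seq_len(nrow(probes)), n_units)
    units <- tibble::tibble(
      unit_id = sprintf("unit_%05d", seq_along(probe_idx)),
      probe_id = probes$probe_id[probe_idx],
      bin_id = probes$bin_id[probe_idx],
      n_cpgs = sample(1:3, length(probe_idx), replace = TRUE)
    )
    th <- theta[units$bin_id, , drop = FALSE]
    vals <- th + matrix(rnorm(length(th), 0, cfg$unit_noise_sd),
                        nrow = nrow(th))
    vals <- pmin(pmax(vals, 0), 1)
    if (cfg$missing_rate > 0) {
      vals[matrix(runif(length(vals)) < cfg$missing_rate,
                  nrow = nrow(vals))] <- NA_real_
    }
    if (cfg$n_high_missing_units > 0 && nrow(units) > 0) {
      forced <- sample(nrow(units),
                       min(cfg$n_high_missing_units, nrow(units)))
      n_miss <- ceiling(0.3 * ncol(vals))
      for (i in forced) {
        vals[i, sample(ncol(vals), n_miss)] <- NA_real_
      }
    }
    colnames(vals) <- meta$sample_id
    list(
      units = units,
      values = dplyr::bind_cols(tibble::tibble(unit_id = units$unit_id),
                                tibble::as_tibble(vals))
    )
  })
}

#' Simulate a complete three-platform cohort
#'
#' Convenience wrapper running [simulate_cohort_meta()],
#' [simulate_bin_counts()], [simulate_probe_betas()] and
#' [simulate_unit_table()] in sequence with a shared configuration.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `meth_cohort`: a list with `meta`, `counts`,
#'   `truth`, `library_sizes`, `probes`, `betas`, `theta`, `units`,
#'   `unit_values` and the originating `config`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_bins = 1000, seed = 42))
#' dim(cohort$counts)
#' }
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  meta <- simulate_cohort_meta(cfg)
  cnt <- simulate_bin_counts(cfg, meta)
  pb <- simulate_probe_betas(cfg, cnt$truth, meta)
  ut <- simulate_unit_table(cfg, pb, meta)
  structure(
    list(meta = meta, counts = cnt$counts, truth = cnt$truth,
         library_sizes = cnt$library_sizes,
         probes = pb$probes, betas = pb$betas, theta = pb$theta,
         units = ut$units, unit_values = ut$values, config = cfg),
    class = "meth_cohort"
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("<meth_cohort>\n")
  cat("  samples:", nrow(x$meta),
      sprintf("(STD %d / EXP %d)", sum(x$meta$arm == "STD"),
              sum(x$meta$arm == "EXP")), "\n")
  cat("  bins:", nrow(x$counts),
      " planted DMRs:", nrow(x$truth), "\n")
  cat("  probes:", nrow(x$probes),
      " CpG units:", nrow(x$units), "\n")
  invisible(x)
}

#' Simulate a random annotation track
#'
#' Builds a toy genomic annotation (transcription start sites, gene models
#' with exons, and per-bin GC fraction) matching a simulated bin grid, for
#' exercising the region-annotation stage on synthetic cohorts.
#'
#' @param cfg A [sim_config()].
#' @param genes_per_chrom Number of gene models per chromosome.
#' @return An annotation track as produced by [make_annotation_track()].
#' @export
simulate_annotation <- function(cfg, genes_per_chrom = 20) {
  bins <- build_bins(cfg)
  withr::with_seed(stage_seed(cfg$seed, 5L), {
    chroms <- split(bins, bins$chrom)
    genes <- purrr::map_dfr(chroms, function(b) {
      len <- max(b$end)
      n_g <- min(genes_per_chrom, max(1, floor(len / 5000)))
      start <- sort(sample(seq(0, max(0, len - 3000)), n_g))
      tibble::tibble(chrom = b$chrom[1], gene_id = paste0(b$chrom[1], "_g",
                                                          seq_len(n_g)),
                     start = start, end = pmin(start + 2500L, len))
    })
    exons <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      n_e <- sample(1:3, 1)
      es <- sort(sample(seq(g$start, g$end - 100, by = 50), n_e))
      tibble::tibble(chrom = g$chrom, gene_id = g$gene_id,
                     start = es, end = pmin(es + 120L, g$end))
    })
    tss <- tibble::tibble(chrom = genes$chrom, pos = genes$start)
    gc <- tibble::tibble(bin_id = bins$bin_id,
                         gc_fraction = rbeta(nrow(bins), 10, 10))
    make_annotation_track(tss = tss, genes = genes, exons = exons, gc = gc)
  })
}
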