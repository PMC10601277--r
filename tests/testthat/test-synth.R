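# Synthetic cohort generator: determinism, bookkeeping, and distributional
# calibration of all three measurement platforms.

test_that("same seed reproduces every generated table exactly", {
  cfg <- tiny_cfg(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$meta, b$meta)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$betas, b$betas)
  expect_identical(a$unit_values, b$unit_values)
  c2 <- simulate_cohort(tiny_cfg(seed = 12))
  expect_false(identical(a$counts, c2$counts))
})

test_that("cohort bookkeeping: arm sizes, required columns, refusal", {
  meta <- simulate_cohort_meta(tiny_cfg(n_samples_per_arm = 20))
  expect_equal(nrow(meta), 40)
  expect_equal(as.integer(table(meta$arm)), c(20L, 20L))
  expect_true(all(!is.na(meta$arm)) && all(!is.na(meta$response)))
  expect_true(all(c("mut_DNMT3A", "karyotype", "age", "sex") %in%
                    names(meta)))
  expect_error(sim_config(n_samples_per_arm = 3), ">= 4")
})

test_that("zero response coefficients give CR fraction logistic(b0)", {
  # binomial-CI oracle: with b0 = 0 the CR rate is 0.5; 600 samples give a
  # 3-sigma band of +/- 3 * sqrt(0.25 / 600)
  meta <- simulate_cohort_meta(
    tiny_cfg(n_samples_per_arm = 300, response_coefficients = c(0),
             seed = 5))
  expect_lt(abs(mean(meta$response == "CR") - 0.5),
            3 * sqrt(0.25 / 600))
})

test_that("zero dispersion and no planted signal give Poisson counts", {
  cfg <- tiny_cfg(n_bins = 200, nb_dispersion = 0, n_planted_dmrs_exp = 0,
                  n_planted_dmrs_std = 0, library_size_cv = 0, seed = 3)
  cnt <- simulate_bin_counts(cfg, simulate_cohort_meta(cfg))
  m <- as.matrix(cnt$counts[, -(1:4)])
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(mean(ratio) - 1), 0.05)
  expect_equal(nrow(cnt$truth), 0)
})

test_that("planted bins realize the configured fold change", {
  # each planted bin is an independent replicate of the planted-effect law;
  # averaging the per-bin CR/RD normalized-count ratio over 500 of them is
  # the Monte-Carlo oracle for the configured 2.5-fold effect
  cfg <- tiny_cfg(n_bins = 2000, n_planted_dmrs_exp = 500,
                  n_planted_dmrs_std = 0, exact_response_fraction = TRUE,
                  response_coefficients = c(0), seed = 8)
  meta <- simulate_cohort_meta(cfg)
  cnt <- simulate_bin_counts(cfg, meta)
  rpkm <- count_matrix_test(compute_rpkm(cnt$counts,
                                         cnt$library_sizes))
  exp_ids <- meta$sample_id[meta$arm == "EXP"]
  resp <- meta$response[match(exp_ids, meta$sample_id)]
  ratios <- vapply(seq_len(nrow(cnt$truth)), function(i) {
    row <- rpkm[cnt$truth$bin_id[i], exp_ids]
    hyper <- if (cnt$truth$direction[i] == "hyper_in_RD") "RD" else "CR"
    mean(row[resp == hyper]) / mean(row[resp != hyper])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2.5), 0.15)
})

test_that("probe coverage follows the configured binomial rate", {
  cfg <- tiny_cfg(n_planted_dmrs_exp = 25, n_planted_dmrs_std = 25,
                  n_null_regions = 50, probe_coverage = 0.8, seed = 21)
  meta <- simulate_cohort_meta(cfg)
  cnt <- simulate_bin_counts(cfg, meta)
  pb <- simulate_probe_betas(cfg, cnt$truth, meta)
  n_regions <- 100
  n_covered <- length(unique(pb$probes$bin_id))
  expect_lt(abs(n_covered - 0.8 * n_regions),
            3 * sqrt(n_regions * 0.8 * 0.2))
  expect_true(all(table(pb$probes$bin_id) <= cfg$max_probes_per_region))
  b <- as.matrix(pb$betas[, -1])
  expect_true(all(b >= 0 & b <= 1))
})

test_that("planted regions show concordant probe-beta differences", {
  # sign-consistency oracle over 200 independently planted regions
  cfg <- tiny_cfg(n_bins = 1000, n_planted_dmrs_exp = 200,
                  n_planted_dmrs_std = 0, n_null_regions = 0,
                  probe_coverage = 1, seed = 13)
  meta <- simulate_cohort_meta(cfg)
  cnt <- simulate_bin_counts(cfg, meta)
  pb <- simulate_probe_betas(cfg, cnt$truth, meta)
  exp_idx <- meta$arm == "EXP"
  rd <- meta$response == "RD"
  agree <- vapply(seq_len(nrow(cnt$truth)), function(i) {
    pr <- pb$probes$probe_id[pb$probes$bin_id == cnt$truth$bin_id[i]]
    if (!length(pr)) return(NA)
    b <- colMeans(as.matrix(
      pb$betas[pb$betas$probe_id %in% pr, -1, drop = FALSE]))
    d <- mean(b[exp_idx & rd]) - mean(b[exp_idx & !rd])
    (cnt$truth$direction[i] == "hyper_in_RD") == (d > 0)
  }, logical(1))
  expect_gte(mean(agree, na.rm = TRUE), 0.95)
})

test_that("unit layer: noise-free values equal theta, missingness binomial", {
  cfg0 <- tiny_cfg(unit_noise_sd = 0, missing_rate = 0, seed = 4)
  co0 <- simulate_cohort(cfg0)
  v <- as.matrix(co0$unit_values[, -1])
  th <- co0$theta[co0$units$bin_id, ]
  expect_equal(unname(v), unname(th), tolerance = 1e-12)
  expect_false(anyNA(v))

  cfg3 <- tiny_cfg(n_samples_per_arm = 50, missing_rate = 0.3, seed = 6)
  co3 <- simulate_cohort(cfg3)
  miss <- rowSums(is.na(as.matrix(co3$unit_values[, -1])))
  expect_lt(abs(mean(miss) - 0.3 * 100), 3 * sqrt(100 * 0.3 * 0.7))
})

test_that("counts, betas and units move coherently at planted regions", {
  cfg <- tiny_cfg(n_bins = 800, n_planted_dmrs_exp = 60,
                  n_planted_dmrs_std = 0, n_null_regions = 0,
                  probe_coverage = 1, seed = 17)
  co <- simulate_cohort(cfg)
  rpkm <- count_matrix_test(compute_rpkm(co$counts, co$library_sizes))
  exp_ids <- co$meta$sample_id[co$meta$arm == "EXP"]
  rd <- co$meta$response[match(exp_ids, co$meta$sample_id)] == "RD"
  coherent <- vapply(seq_len(nrow(co$truth)), function(i) {
    bin <- co$truth$bin_id[i]
    cdiff <- mean(rpkm[bin, exp_ids][rd]) - mean(rpkm[bin, exp_ids][!rd])
    pr <- co$probes$probe_id[co$probes$bin_id == bin]
    un <- co$units$unit_id[co$units$bin_id == bin]
    if (!length(pr) || !length(un)) return(NA)
    bmat <- as.matrix(co$betas[co$betas$probe_id %in% pr, exp_ids,
                               drop = FALSE])
    umat <- as.matrix(co$unit_values[co$unit_values$unit_id %in% un,
                                     exp_ids, drop = FALSE])
    bdiff <- mean(colMeans(bmat)[rd]) - mean(colMeans(bmat)[!rd])
    udiff <- mean(umat[, rd], na.rm = TRUE) -
      mean(umat[, !rd], na.rm = TRUE)
    sign(cdiff) == sign(bdiff) && sign(bdiff) == sign(udiff)
  }, logical(1))
  expect_gte(mean(coherent, na.rm = TRUE), 0.95)
})

test_that("arm overlap switch plants shared bins; default keeps arms disjoint", {
  cfg <- tiny_cfg(seed = 9, exact_response_fraction = TRUE)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  expect_length(intersect(tr$bin_id[tr$arm == "EXP"],
                          tr$bin_id[tr$arm == "STD"]), 0)
  cfg2 <- tiny_cfg(seed = 9, arm_overlap = TRUE,
                   exact_response_fraction = TRUE)
  tr2 <- simulate_bin_counts(cfg2, simulate_cohort_meta(cfg2))$truth
  expect_gt(length(intersect(tr2$bin_id[tr2$arm == "EXP"],
                             tr2$bin_id[tr2$arm == "STD"])), 0)
})

test_that("low-count outlier switch produces a sub-threshold library", {
  cfg <- tiny_cfg(n_lowcount_outliers = 1, library_size_mean = 5e6,
                  seed = 2)
  cnt <- simulate_bin_counts(cfg, simulate_cohort_meta(cfg))
  expect_equal(sum(cnt$library_sizes < 1e6), 1)
})
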