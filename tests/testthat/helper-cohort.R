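# small, fast default configurations used across tests
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(
    n_samples_per_arm = 10, n_bins = 400, n_planted_dmrs_exp = 10,
    n_planted_dmrs_std = 10, n_null_regions = 15,
    library_size_mean = 2e5, n_lowcount_outliers = 0, seed = 1
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# wide count tibble from a plain matrix
as_counts <- function(m, chrom = "chr1") {
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(bin_id = sprintf("b%04d", seq_len(nrow(m))),
                   chrom = chrom,
                   start = (seq_len(nrow(m)) - 1L) * 500L,
                   end = seq_len(nrow(m)) * 500L),
    tibble::as_tibble(m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample-column matrix of a wide bin tibble (test-side mirror of the
# package-internal accessor)
count_matrix_test <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts),
                                  c("bin_id", "chrom", "start", "end"))])
  rownames(m) <- counts$bin_id
  m
}
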