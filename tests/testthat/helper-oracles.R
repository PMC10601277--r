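# Independent brute-force oracle: per-character conversion, strand handling,
# scan-and-split at U, and a direct mass lookup.
oracle_fragments <- function(seq, reaction) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  conv <- chars
  for (i in seq_len(L)) {
    if (conv[i] == "C" && (i == L || chars[i + 1] != "G")) conv[i] <- "T"
  }
  cpg_c <- which(chars == "C" & c(chars[-1], "") == "G")
  if (reaction == "T_reverse") {
    conv <- rev(unname(comp[conv]))
    cpg_c <- L - cpg_c
  }
  conv[conv == "T"] <- "U"
  masses <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
  frags <- list()
  cur <- integer(0)
  for (i in seq_along(conv)) {
    cur <- c(cur, i)
    if (conv[i] == "U" || i == length(conv)) {
      frags[[length(frags) + 1]] <- cur
      cur <- integer(0)
    }
  }
  purrr::map_dfr(frags, function(idx) {
    tibble::tibble(
      sequence = paste(conv[idx], collapse = ""),
      base_mass = sum(masses[conv[idx]]) + 18.02,
      n_cpgs = sum(cpg_c %in% idx)
    )
  })
}
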