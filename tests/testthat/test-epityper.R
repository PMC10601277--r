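# In-silico EpiTYPER layer: fragmentation against a brute-force oracle,
# mass shifts, unit informativeness, design constraints, and unit-matrix QC.


test_that("fragmentation equals the brute-force oracle on random amplicons", {
  set.seed(14)
  for (i in 1:30) {
    seq <- random_dna(300, gc = runif(1, 0.3, 0.7))
    for (reaction in c("T_forward", "T_reverse")) {
      mine <- bisulfite_and_fragment(seq, reaction)
      ref <- oracle_fragments(seq, reaction)
      expect_equal(mine$sequence, ref$sequence)
      expect_equal(mine$base_mass, ref$base_mass, tolerance = 1e-9)
      expect_equal(mine$n_cpgs, ref$n_cpgs)
    }
  }
})

test_that("methylation shifts fragment mass by exactly 16 Da per CpG", {
  set.seed(15)
  frags <- bisulfite_and_fragment(random_dna(300, gc = 0.6))
  for (i in which(frags$n_cpgs > 0)) {
    k <- sample(0:frags$n_cpgs[i], 1)
    expect_equal(fragment_mass(frags$base_mass[i], k) -
                   frags$base_mass[i], 16 * k)
  }
  # two methylated CpGs shift by +32
  two <- which(frags$n_cpgs == 2)
  if (length(two)) {
    expect_equal(fragment_mass(frags$base_mass[two[1]], 2) -
                   frags$base_mass[two[1]], 32)
  }
})

test_that("a transcript without U yields a single spanning fragment", {
  # all-A amplicon: conversion leaves no T, so no cleavage on the forward
  # transcript
  frags <- bisulfite_and_fragment(strrep("A", 40), "T_forward")
  expect_equal(nrow(frags), 1)
  expect_equal(frags$length, 40L)
})

test_that("unit informativeness: window and collision rules", {
  frags <- tibble::tibble(
    fragment_id = c("f1", "f2", "f3", "f4"),
    base_mass = c(3000, 3000.5, 5000, 800),  # f1/f2 collide; f4 below window
    n_cpgs = c(1L, 1L, 2L, 1L),
    cpg_sites = list(1L, 5L, c(9L, 13L), 17L)
  )
  units <- assign_cpg_units(frags, mass_window = c(1500, 7000),
                            tolerance = 1.0)
  expect_equal(nrow(units), 4)  # every CpG-bearing fragment forms a unit
  expect_false(units$informative[units$fragment_id == "f1"])
  expect_false(units$informative[units$fragment_id == "f2"])
  expect_true(units$informative[units$fragment_id == "f3"])
  expect_false(units$informative[units$fragment_id == "f4"])
  expect_match(units$reason[units$fragment_id == "f4"], "window")
  # a CpG-free fragment never forms a unit
  frags0 <- tibble::tibble(fragment_id = "f0", base_mass = 4000,
                           n_cpgs = 0L, cpg_sites = list(integer(0)))
  expect_equal(nrow(assign_cpg_units(frags0)), 0)
})

test_that("collision rule agrees with brute-force mass-state enumeration", {
  set.seed(16)
  frags <- bisulfite_and_fragment(random_dna(350, gc = 0.65))
  units <- assign_cpg_units(frags)
  # oracle: enumerate every mass state of every fragment and test overlap
  states <- lapply(seq_len(nrow(frags)), function(i) {
    frags$base_mass[i] + 16 * (0:frags$n_cpgs[i])
  })
  for (u in seq_len(nrow(units))) {
    i <- match(units$fragment_id[u], frags$fragment_id)
    st <- states[[i]]
    others <- unlist(states[-i])
    ok_window <- all(st >= 1500 & st <= 7000)
    ok_coll <- !length(others) || min(outer(st, others,
                                            function(a, b) abs(a - b))) > 1
    expect_equal(units$informative[u], ok_window && ok_coll)
  }
})

test_that("assay design hard constraints are enforced", {
  fwd <- "TGGATTAGGTTAGGTTGGATTGG"   # 23 bp, CG-free
  rev <- "CCAATCCAACCTAACCTAATCCA"   # 23 bp, CG-free
  ok_seq <- random_dna(300, gc = 0.5)

  long <- make_assay("a1", random_dna(600), fwd, rev)
  expect_false(check_assay_design(long)$pass)
  expect_match(paste(check_assay_design(long)$violations, collapse = " "),
               "length")

  cg_primer <- make_assay("a2", ok_seq, "TGGATTAGGTCGGGTTGGATTGG", rev)
  expect_match(paste(check_assay_design(cg_primer)$violations,
                     collapse = " "), "CpG")

  short_primer <- make_assay("a3", ok_seq, "TGGAT", rev)
  res <- check_assay_design(short_primer)
  expect_match(paste(res$violations, collapse = " "), "Tm difference")

  # a CpG-free amplicon has informative ratio 0 and fails that gate
  no_cpg <- make_assay("a4", gsub("CG", "CA", ok_seq), fwd, rev)
  res4 <- check_assay_design(no_cpg)
  expect_match(paste(res4$violations, collapse = " "), "informative")

  expect_error(make_assay("a5", "ACGTN", fwd, rev), "non-DNA")
})

test_that("nearest-neighbor Tm behaves sensibly", {
  # GC-rich primers melt higher; longer primers melt higher
  expect_gt(primer_tm("GGCCGGCCGGCCGGCCGGCC"), primer_tm("ATTATTATTATTATTATTAT"))
  expect_gt(primer_tm(strrep("GATC", 8)), primer_tm(strrep("GATC", 4)))
  tm <- primer_tm("TGGATTAGGTTAGGTTGGATTGG")
  expect_true(tm > 30 && tm < 80)
})

test_that("unit QC drops >20% missing, imputes, and aggregates by mean", {
  n_s <- 100
  mk <- function(vals) setNames(as.list(vals), sprintf("s%03d", 1:n_s))
  base <- rep(0.7, n_s)
  v21 <- base; v21[1:21] <- NA           # 21% missing: dropped
  v20 <- base; v20[1:20] <- NA           # 20% missing: kept
  values <- dplyr::bind_rows(
    tibble::tibble(unit_id = "u21", !!!mk(v21)),
    tibble::tibble(unit_id = "u20", !!!mk(v20)),
    tibble::tibble(unit_id = "d1", !!!mk(base)),
    tibble::tibble(unit_id = "d2", !!!mk(base)),
    tibble::tibble(unit_id = "d3", !!!mk(base)),
    tibble::tibble(unit_id = "d4", !!!mk(base)),
    tibble::tibble(unit_id = "d5", !!!mk(base))
  )
  manifest <- tibble::tibble(
    unit_id = c("u21", "u20", "d1", "d2", "d3", "d4", "d5"),
    probe_id = c("pA", "pA", "pB", "pB", "pC", "pC", "pC")
  )
  out <- process_unit_matrix(values, manifest, k = 5)
  expect_equal(out$dropped, "u21")
  expect_true("u20" %in% out$units$unit_id)
  # the five donors all read 0.7 at the missing samples
  imputed <- as.matrix(out$units[out$units$unit_id == "u20", -1])
  expect_equal(unname(imputed[1, 1:20]), rep(0.7, 20))
  expect_false(anyNA(as.matrix(out$units[, -1])))
  expect_equal(out$n_imputed, 20L)
})

test_that("imputation preserves observed entries; aggregation means units", {
  set.seed(30)
  n_s <- 12
  v <- matrix(runif(6 * n_s), nrow = 6)
  colnames(v) <- paste0("s", 1:n_s)
  miss <- cbind(c(1, 3), c(2, 7))
  v_na <- v; v_na[miss] <- NA
  values <- dplyr::bind_cols(tibble::tibble(unit_id = paste0("u", 1:6)),
                             tibble::as_tibble(v_na))
  manifest <- tibble::tibble(unit_id = paste0("u", 1:6),
                             probe_id = rep(c("p1", "p2", "p3"), each = 2))
  out <- process_unit_matrix(values, manifest, k = 3)
  got <- as.matrix(out$units[, -1])
  expect_equal(got[-c(1, 3), ], v[-c(1, 3), ], ignore_attr = TRUE)
  expect_equal(got[1, -2], v[1, -2], ignore_attr = TRUE)
  expect_false(anyNA(got))
  # probe aggregate is the unit mean
  agg <- as.matrix(out$probes[, -1])
  expect_equal(agg[which(out$probes$probe_id == "p3"), ],
               colMeans(got[5:6, ]), ignore_attr = TRUE)

  # two units 0.4 and 0.6 aggregate to 0.5
  vals2 <- tibble::tibble(unit_id = c("x1", "x2"), sA = c(0.4, 0.6),
                          sB = c(0.2, 0.8))
  man2 <- tibble::tibble(unit_id = c("x1", "x2"), probe_id = "pX")
  out2 <- process_unit_matrix(vals2, man2)
  expect_equal(unname(as.matrix(out2$probes[, -1])[1, ]), c(0.5, 0.5))
})
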