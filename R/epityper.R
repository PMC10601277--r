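# In-silico EpiTYPER mass-spectrometry layer: bisulfite conversion,
# U-specific cleavage fragmentation of the in vitro transcript, fragment
# mass prediction (+16 Da per methylated CpG), CpG-unit derivation and
# informativeness, assay design constraint checking, and unit-matrix QC
# (missingness filter, kNN imputation, unit-to-probe aggregation).

# average ribonucleotide masses (Da); only mass differences (G - A = 16)
# are contract-critical, the absolute values are a stated convention
RNA_MASSES <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
TERMINAL_MASS <- 18.02
METHYL_SHIFT <- 16

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(seq) {
  paste(rev(DNA_COMP[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

check_dna <- function(seq) {
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains non-DNA characters (A/C/G/T only)",
         call. = FALSE)
  }
  invisible(seq)
}

#' In-silico bisulfite conversion
#'
#' Converts every cytosine to thymine except the cytosine of a CpG
#' dinucleotide, which is the variable (methylation-readout) site.
#'
#' @param seq DNA string (A/C/G/T).
#' @return Converted sequence.
#' @examples
#' bisulfite_convert("ACGCAT")  # "ACGTAT"
#' @export
bisulfite_convert <- function(seq) {
  check_dna(toupper(seq))
  gsub("C(?!G)", "T", toupper(seq), perl = TRUE)
}

#' Bisulfite conversion and U-specific cleavage fragmentation
#'
#' Models the EpiTYPER T-cleavage reaction: the amplicon is bisulfite
#' converted (CpG cytosines preserved), the strand addressed by `reaction`
#' is transcribed into RNA (T becomes U; `T_reverse` transcribes the
#' reverse complement, as when the T7 tag sits on the reverse primer), and
#' the transcript is cleaved after every U. Each maximal inter-cleavage run
#' is a fragment. The base mass of a fragment sums the configured
#' ribonucleotide masses plus a terminal water adjustment and is computed
#' with all CpG sites unmethylated; every methylated member CpG adds
#' +16 Da.
#'
#' @param seq Amplicon DNA sequence.
#' @param reaction `"T_reverse"` (default) or `"T_forward"`.
#' @param masses Named ribonucleotide mass vector (Da).
#' @param terminal Terminal mass adjustment (Da).
#' @return Tibble with one row per fragment: `fragment_id`, `start`, `end`
#'   (1-based positions in the transcript), `sequence`, `length`,
#'   `base_mass`, `n_cpgs`, and `cpg_sites` (list column of 1-based
#'   positions of the member CpGs' cytosines in the input sequence).
#' @examples
#' frags <- bisulfite_and_fragment("ACGGATCGA", reaction = "T_forward")
#' frags$sequence
#' @export
bisulfite_and_fragment <- function(seq, reaction = c("T_reverse",
                                                     "T_forward"),
                                   masses = RNA_MASSES,
                                   terminal = TERMINAL_MASS) {
  reaction <- match.arg(reaction)
  seq <- toupper(seq)
  check_dna(seq)
  L <- nchar(seq)
  cpg <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  cpg <- if (cpg[1] == -1) integer(0) else as.integer(cpg)
  conv <- bisulfite_convert(seq)
  if (reaction == "T_reverse") {
    work <- revcomp(conv)
    # original CpG cytosine at i pairs with the G at i+1, whose complement
    # C sits at L - i in the reverse strand
    cpg_work <- L - cpg
  } else {
    work <- conv
    cpg_work <- cpg
  }
  transcript <- chartr("T", "U", work)
  chars <- strsplit(transcript, "", fixed = TRUE)[[1]]
  u_pos <- which(chars == "U")
  ends <- sort(unique(c(u_pos, length(chars))))
  starts <- c(1L, ends[-length(ends)] + 1L)
  frag <- purrr::map_dfr(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    fchars <- chars[s:e]
    members <- cpg[cpg_work >= s & cpg_work <= e]
    tibble::tibble(
      fragment_id = sprintf("frag_%03d", i),
      start = s, end = e,
      sequence = paste(fchars, collapse = ""),
      length = e - s + 1L,
      base_mass = sum(masses[fchars]) + terminal,
      n_cpgs = length(members),
      cpg_sites = list(members)
    )
  })
  frag
}

#' Fragment mass under a methylation state
#'
#' @param base_mass Fragment base mass (all member CpGs unmethylated).
#' @param n_methylated Number of methylated member CpGs.
#' @return Mass in Da (`base + 16 * n_methylated`).
#' @export
fragment_mass <- function(base_mass, n_methylated = 0) {
  base_mass + METHYL_SHIFT * n_methylated
}

#' Derive CpG units and their informativeness from a fragment table
#'
#' CpGs sharing a cleavage fragment form one CpG unit and are quantified
#' jointly. A unit is informative iff every one of its mass states
#' (`base + 16k` Da for `k = 0..n_cpgs`) lies inside the detectable mass
#' window and none collides, within `tolerance`, with any mass state of a
#' different fragment of the same assay.
#'
#' @param fragments Fragment tibble from [bisulfite_and_fragment()].
#' @param mass_window Detectable mass window in Da (default 1500..7000).
#' @param tolerance Mass collision tolerance in Da (default 1.0).
#' @return Tibble of CpG units: `unit_id`, `fragment_id`, `n_cpgs`,
#'   `cpg_sites` (list), `base_mass`, `informative`, `reason`.
#' @export
assign_cpg_units <- function(fragments, mass_window = c(1500, 7000),
                             tolerance = 1.0) {
  states <- lapply(seq_len(nrow(fragments)), function(i) {
    fragment_mass(fragments$base_mass[i], 0:fragments$n_cpgs[i])
  })
  unit_rows <- which(fragments$n_cpgs > 0)
  if (!length(unit_rows)) {
    return(tibble::tibble(unit_id = character(), fragment_id = character(),
                          n_cpgs = integer(), cpg_sites = list(),
                          base_mass = numeric(), informative = logical(),
                          reason = character()))
  }
  out <- purrr::map_dfr(seq_along(unit_rows), function(u) {
    i <- unit_rows[u]
    st <- states[[i]]
    in_window <- all(st >= mass_window[1] & st <= mass_window[2])
    others <- unlist(states[-i], use.names = FALSE)
    collision <- length(others) > 0 &&
      min(vapply(st, function(s) min(abs(others - s)), numeric(1))) <=
        tolerance
    reason <- if (!in_window) "mass state outside detectable window"
      else if (collision) "mass collision with another fragment"
      else NA_character_
    tibble::tibble(
      unit_id = sprintf("unit_%03d", u),
      fragment_id = fragments$fragment_id[i],
      n_cpgs = fragments$n_cpgs[i],
      cpg_sites = fragments$cpg_sites[i],
      base_mass = fragments$base_mass[i],
      informative = in_window && !collision,
      reason = reason
    )
  })
  out
}

# SantaLucia (unified) nearest-neighbor parameters: dH kcal/mol, dS cal/(mol K)
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Primer melting temperature by nearest-neighbor thermodynamics
#'
#' Unified nearest-neighbor model with terminal initiation corrections and
#' an entropic monovalent-salt correction;
#' `Tm = dH / (dS + R ln(C/4)) - 273.15`.
#'
#' @param seq Primer sequence.
#' @param primer_nM Primer concentration in nM (default 500).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @return Melting temperature in degrees Celsius.
#' @export
primer_tm <- function(seq, primer_nM = 500, na_mM = 50) {
  seq <- toupper(seq)
  check_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 2) stop("primer too short", call. = FALSE)
  nn <- paste0(chars[-length(chars)], chars[-1])
  dh <- sum(NN_DH[nn])
  ds <- sum(NN_DS[nn])
  for (term in chars[c(1, length(chars))]) {
    if (term %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (length(chars) - 1) * log(na_mM / 1000)
  dh * 1000 / (ds + 1.987 * log(primer_nM * 1e-9 / 4)) - 273.15
}

#' Construct an amplicon assay
#'
#' @param amplicon_id Assay identifier.
#' @param sequence Genomic amplicon sequence (A/C/G/T).
#' @param fwd_primer,rev_primer Primer sequences (as synthesized).
#' @param reaction Cleavage reaction strand (`"T_reverse"` default).
#' @return An `amplicon_assay` list.
#' @export
make_assay <- function(amplicon_id, sequence, fwd_primer, rev_primer,
                       reaction = c("T_reverse", "T_forward")) {
  reaction <- match.arg(reaction)
  sequence <- toupper(sequence); check_dna(sequence)
  fwd_primer <- toupper(fwd_primer); check_dna(fwd_primer)
  rev_primer <- toupper(rev_primer); check_dna(rev_primer)
  structure(list(amplicon_id = amplicon_id, sequence = sequence,
                 fwd_primer = fwd_primer, rev_primer = rev_primer,
                 reaction = reaction),
            class = "amplicon_assay")
}

#' Check an assay design against EpiTYPER constraints
#'
#' Hard constraints: amplicon length 200-500 bp; no CG dinucleotide in
#' either primer (primers must not overlap variable sites); annealing
#' temperature difference between the primers at most 5 degrees C; ratio of
#' CpGs in informative units to total amplicon CpGs at least
#' `min_informative_ratio` (default 0.7). Soft scores report primer length
#' closeness to the ideal 22-25 bp, Tm closeness to 60 degrees C, overall
#' thymine content (lower is better) and 3'-end cytosine richness (higher
#' is better).
#'
#' @param assay An [make_assay()] object.
#' @param min_informative_ratio Required informative-to-total CpG ratio.
#' @param mass_window,tolerance Passed to [assign_cpg_units()].
#' @return List with `pass` (logical), `violations` (character vector),
#'   `informative_ratio`, `tm` (named forward/reverse), and `scores`
#'   (one-row tibble of soft scores).
#' @export
check_assay_design <- function(assay, min_informative_ratio = 0.7,
                               mass_window = c(1500, 7000),
                               tolerance = 1.0) {
  stopifnot(inherits(assay, "amplicon_assay"))
  violations <- character(0)
  len <- nchar(assay$sequence)
  if (len < 200 || len > 500) {
    violations <- c(violations,
                    sprintf("amplicon length %d outside 200-500 bp", len))
  }
  for (p in c("fwd_primer", "rev_primer")) {
    if (grepl("CG", assay[[p]], fixed = TRUE)) {
      violations <- c(violations,
                      paste(p, "contains a CpG dinucleotide"))
    }
  }
  tm_f <- primer_tm(assay$fwd_primer)
  tm_r <- primer_tm(assay$rev_primer)
  if (abs(tm_f - tm_r) > 5) {
    violations <- c(violations,
                    sprintf("primer Tm difference %.1f exceeds 5 degrees C",
                            abs(tm_f - tm_r)))
  }
  n_cpg_total <- length(gregexpr("CG", assay$sequence,
                                 fixed = TRUE)[[1]][
    gregexpr("CG", assay$sequence, fixed = TRUE)[[1]] > 0])
  frags <- bisulfite_and_fragment(assay$sequence, assay$reaction)
  units <- assign_cpg_units(frags, mass_window, tolerance)
  n_informative <- sum(units$n_cpgs[units$informative])
  ratio <- if (n_cpg_total == 0) 0 else n_informative / n_cpg_total
  if (ratio < min_informative_ratio) {
    violations <- c(violations,
                    sprintf("informative CpG ratio %.2f below %.2f",
                            ratio, min_informative_ratio))
  }
  t_content <- function(p) {
    mean(strsplit(p, "", fixed = TRUE)[[1]] == "T")
  }
  c3_rich <- function(p) {
    tail5 <- substring(p, max(1, nchar(p) - 4), nchar(p))
    mean(strsplit(tail5, "", fixed = TRUE)[[1]] == "C")
  }
  scores <- tibble::tibble(
    fwd_length_ok = nchar(assay$fwd_primer) >= 22 &
      nchar(assay$fwd_primer) <= 25,
    rev_length_ok = nchar(assay$rev_primer) >= 22 &
      nchar(assay$rev_primer) <= 25,
    fwd_tm_dev = abs(tm_f - 60), rev_tm_dev = abs(tm_r - 60),
    fwd_t_content = t_content(assay$fwd_primer),
    rev_t_content = t_content(assay$rev_primer),
    fwd_c3_richness = c3_rich(assay$fwd_primer),
    rev_c3_richness = c3_rich(assay$rev_primer)
  )
  list(pass = length(violations) == 0, violations = violations,
       informative_ratio = ratio, tm = c(forward = tm_f, reverse = tm_r),
       scores = scores)
}

#' QC, impute and aggregate a CpG-unit methylation matrix
#'
#' Drops units with strictly more than `max_missing` missing values,
#' imputes the remaining missing entries by the mean of the `k` nearest
#' units (Euclidean distance on pairwise-complete sample vectors; only
#' units observed at the target sample qualify as donors), and aggregates
#' units to their parent probe by the arithmetic mean. Observed entries are
#' never altered and the output carries no missing values.
#'
#' @param values Wide unit tibble (`unit_id` x samples, `NA` = missing).
#' @param unit_manifest Optional tibble mapping `unit_id` to `probe_id`
#'   for aggregation; without it only the imputed unit matrix is returned.
#' @param max_missing Maximum tolerated missing fraction (default 0.2,
#'   strictly greater is dropped).
#' @param k Number of neighbor units used for imputation (default 5; if
#'   fewer donors exist, all available are used with a warning).
#' @return List with `units` (clean imputed unit matrix), `probes`
#'   (probe-aggregated matrix, `NULL` without a manifest), `dropped`
#'   (unit ids removed by the missingness filter) and `n_imputed`.
#' @export
process_unit_matrix <- function(values, unit_manifest = NULL,
                                max_missing = 0.2, k = 5) {
  v <- as.matrix(values[, setdiff(names(values), "unit_id"), drop = FALSE])
  rownames(v) <- values$unit_id
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop("unit methylation values must lie in [0, 1]", call. = FALSE)
  }
  miss_frac <- rowMeans(is.na(v))
  dropped <- rownames(v)[miss_frac > max_missing]
  v <- v[miss_frac <= max_missing, , drop = FALSE]
  if (nrow(v) == 0) stop("no units survive the missingness filter",
                         call. = FALSE)

  n_imputed <- 0L
  if (anyNA(v)) {
    obs <- !is.na(v)
    x0 <- v; x0[!obs] <- 0
    shared <- obs %*% t(obs)
    q <- (x0^2) %*% t(obs)
    d2 <- (q + t(q) - 2 * x0 %*% t(x0)) / shared
    d2[shared == 0] <- Inf
    diag(d2) <- Inf
    warned <- FALSE
    for (i in which(rowSums(!obs) > 0)) {
      for (s in which(!obs[i, ])) {
        donors <- which(obs[, s])
        donors <- donors[is.finite(d2[i, donors])]
        if (!length(donors)) {
          v[i, s] <- mean(v[i, ], na.rm = TRUE)
        } else {
          if (length(donors) < k && !warned) {
            warning("fewer than k = ", k, " donor units available for ",
                    "some imputations; using all available", call. = FALSE)
            warned <- TRUE
          }
          near <- donors[order(d2[i, donors])][seq_len(min(k,
                                                           length(donors)))]
          v[i, s] <- mean(v[near, s])
        }
        n_imputed <- n_imputed + 1L
      }
    }
  }
  units_out <- dplyr::bind_cols(tibble::tibble(unit_id = rownames(v)),
                                tibble::as_tibble(v))
  probes_out <- NULL
  if (!is.null(unit_manifest)) {
    map <- unit_manifest$probe_id[match(rownames(v),
                                        unit_manifest$unit_id)]
    agg <- rowsum(v, group = map) / as.vector(table(map)[sort(unique(map))])
    agg <- agg[order(rownames(agg)), , drop = FALSE]
    probes_out <- dplyr::bind_cols(tibble::tibble(probe_id = rownames(agg)),
                                   tibble::as_tibble(agg))
  }
  list(units = units_out, probes = probes_out, dropped = dropped,
       n_imputed = n_imputed)
}

#' Random DNA sequence
#'
#' Convenience generator for synthetic amplicons.
#'
#' @param n Length in bp.
#' @param gc GC fraction.
#' @return A DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
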