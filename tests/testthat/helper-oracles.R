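# Independent oracles and fixture builders used across the suite.  Each
# oracle recomputes the quantity under test by a different route than the
# implementation (elemental compositions, exhaustive enumeration, one-pass
# set logic) so agreement is informative.

# ---- fragment masses from elemental compositions ---------------------------
# Residue formulas (residue = amino acid minus water) and monoisotopic
# element masses; deliberately independent of the package's residue-mass
# table.
.elem <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)
.formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)
.proton_oracle <- 1.00727646688
.water_oracle <- 2 * .elem[["H"]] + .elem[["O"]]

oracle_residue_mass <- function(aa) {
  f <- .formulas[[aa]]
  sum(.elem[names(f)] * f)
}

oracle_fragment_mz <- function(peptide) {
  res <- vapply(strsplit(peptide, "")[[1]], oracle_residue_mass, numeric(1))
  L <- length(res)
  idx <- seq_len(L - 1)
  list(b = unname(cumsum(res)[idx] + .proton_oracle),
       y = unname(cumsum(rev(res))[idx] + .water_oracle + .proton_oracle),
       neutral = sum(res) + .water_oracle)
}

# ---- one-pass set-logic oracle for the filter ladder ------------------------
oracle_ladder_retained <- function(psms, config) {
  q <- psms$q_value
  if (all(is.na(q))) q <- estimate_q_values(psms$score, psms$is_decoy)
  ok <- q <= config$fdr_cutoff &
    !psms$is_decoy &
    !(psms$sequence %in% config$irt_peptides) &
    !(psms$sequence %in% config$blank_peptides) &
    (!config$drop_modified | !nzchar(psms$modifications)) &
    nchar(psms$sequence) >= config$length_min &
    nchar(psms$sequence) <= config$length_max
  sort(unique(psms$sequence[ok]))
}

# ---- exhaustive hypergeometric tail (N small) -------------------------------
oracle_hyper_tail <- function(N, K, n, x) {
  combos <- utils::combn(N, n)
  hits <- colSums(matrix(combos <= K, nrow = n))
  mean(hits >= x)
}

# ---- membership-vector tally for exclusive intersections --------------------
oracle_upset <- function(sets) {
  u <- unique(unlist(sets))
  pat <- vapply(u, function(m) {
    paste(names(sets)[vapply(sets, function(s) m %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(pat)
}

# ---- small fixture builders -------------------------------------------------
random_psm_fixture <- function(seed) {
  set.seed(seed)
  n_true <- sample(20:60, 1)
  peptides <- unique(vapply(seq_len(n_true), function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 sample(7:13, 1), replace = TRUE), collapse = "")
  }, character(1)))
  make_psm_dataset(peptides,
                   n_decoy = sample(0:10, 1) + 2L,
                   n_irt = sample(0:5, 1),
                   n_blank = sample(0:5, 1),
                   n_modified = sample(0:5, 1),
                   seed = seed + 1)
}

canonical_psm_fixture <- function() {
  data.frame(
    sequence = c("SIINFEKL", "SLLQHLIGL", "IVDPGYLGY"),
    modifications = c("4|Oxidation", "", ""),
    score = c(31.5, 28.0, 35.2),
    q_value = c(0.01, 0.02, 0.001),
    is_decoy = c(FALSE, FALSE, FALSE),
    sample = c("S1", "S1", "S2"),
    antibody = c("pan-classI", "pan-classI", "A2"),
    rt_min = c(45.2, 74.9, 73.9),
    intensity = c(1e6, 2e6, 3e6),
    proteins = c("P01234", "P06239;P01234", "Q14627"),
    stringsAsFactors = FALSE
  )
}
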