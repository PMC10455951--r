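# Synthetic-peptide spectral validation: theoretical b/y fragmentation,
# tolerance matching of observed peaks onto the fragment basis, mirror
# Pearson correlation and the retention-time window decision rule.

# Monoisotopic residue masses (Da) and physical constants.
IP_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
IP_PROTON <- 1.00727646688
IP_WATER <- 18.0105646863

ip_residue_masses <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  unknown <- setdiff(aa, names(IP_MONO_MASS))
  if (length(unknown) > 0L) {
    ip_stop("unknown amino acid letter(s): ", paste(unknown, collapse = ", "),
            class = "immunopept_format_error")
  }
  unname(IP_MONO_MASS[aa])
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water (the intact peptide).
#'
#' @param peptide amino-acid string over the 20-letter alphabet.
#' @return mass in Da.
#' @export
peptide_mass <- function(peptide) {
  sum(ip_residue_masses(peptide)) + IP_WATER
}

#' Precursor m/z of a peptide at a given charge
#'
#' @inheritParams peptide_mass
#' @param charge positive integer charge state.
#' @export
precursor_mz <- function(peptide, charge = 1L) {
  (peptide_mass(peptide) + charge * IP_PROTON) / charge
}

#' Theoretical b/y fragment ions of a peptide
#'
#' For a peptide of length L, the singly-charged series are
#' `b_i = sum(residues 1..i) + proton` and
#' `y_i = sum(residues L-i+1..L) + water + proton`, i in 1..L-1 (2(L-1)
#' fragments).  With `max_charge = 2` the doubly-charged ions
#' `(mz1 + proton)/2` are appended.
#'
#' @inheritParams peptide_mass
#' @param max_charge 1 (default) or 2.
#' @return data frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz` and `label` (e.g. `"b3+"`).
#' @export
theoretical_fragments <- function(peptide, max_charge = 1L) {
  res <- ip_residue_masses(peptide)
  L <- length(res)
  if (L < 2L) {
    ip_stop("peptide must have at least two residues",
            class = "immunopept_format_error")
  }
  idx <- seq_len(L - 1L)
  b <- cumsum(res)[idx] + IP_PROTON
  # y_i spans the C-terminal i residues
  y <- cumsum(rev(res))[idx] + IP_WATER + IP_PROTON
  out <- data.frame(
    series = rep(c("b", "y"), each = L - 1L),
    index = c(idx, idx),
    charge = 1L,
    mz = c(b, y),
    stringsAsFactors = FALSE
  )
  if (max_charge >= 2L) {
    two <- out
    two$charge <- 2L
    two$mz <- (two$mz + IP_PROTON) / 2
    out <- rbind(out, two)
  }
  out$label <- paste0(out$series, out$index,
                      strrep("+", out$charge))
  out
}

#' Project two spectra onto a shared theoretical-fragment intensity basis
#'
#' For each theoretical fragment, each spectrum contributes the intensity of
#' its nearest peak within `tol_da`; fragments with no peak in the window
#' contribute 0.  Both returned vectors therefore have length
#' `nrow(fragments)`.
#'
#' @param spectrum_a,spectrum_b `spectrum` objects.
#' @param fragments data frame from [theoretical_fragments()].
#' @param tol_da fragment-ion matching tolerance in Da (default 0.02).
#' @return list with numeric vectors `a` and `b`.
#' @export
match_intensity_vectors <- function(spectrum_a, spectrum_b, fragments,
                                    tol_da = 0.02) {
  if (tol_da <= 0) ip_stop("tol_da must be positive")
  project <- function(sp) {
    mz <- sp$peaks[, "mz"]
    int <- sp$peaks[, "intensity"]
    vapply(fragments$mz, function(target) {
      if (length(mz) == 0L) return(0)
      d <- abs(mz - target)
      j <- which.min(d)
      if (d[j] <= tol_da) int[j] else 0
    }, numeric(1))
  }
  list(a = project(spectrum_a), b = project(spectrum_b))
}

#' Mirror Pearson correlation between two matched intensity vectors
#'
#' @param vec_a,vec_b equal-length numeric vectors (length >= 3).  A
#'   zero-variance vector makes the correlation undefined and raises a
#'   condition of class `immunopept_zero_variance`.
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
mirror_pearson <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b) || length(vec_a) < 3L) {
    ip_stop("vectors must have equal length >= 3")
  }
  if (stats::sd(vec_a) == 0 || stats::sd(vec_b) == 0) {
    ip_stop("correlation undefined: zero-variance intensity vector",
            class = "immunopept_zero_variance")
  }
  stats::cor(vec_a, vec_b)
}

#' Validate an endogenous spectrum against its synthetic standard
#'
#' Computes the mirror Pearson correlation over the peptide's theoretical
#' b/y fragment basis and applies the decision rule
#' `R >= r_min` (AND `|RT_endogenous - RT_synthetic| <= rt_window_min` when
#' the retention-time rule is enabled).  The RT rule is off by default: the
#' correlation criterion is the primary evidence of identity, and observed
#' chromatographic shifts between endogenous and synthetic runs can
#' legitimately exceed a fixed window.
#'
#' @param endogenous,synthetic `spectrum` objects of the same peptide.
#' @param peptide the peptide sequence.
#' @param r_min minimum passing correlation (default 0.9).
#' @param rt_window_min retention-time window in minutes (default 3).
#' @param rt_rule_enabled apply the RT window in the decision (default
#'   `FALSE`).
#' @param tol_da fragment matching tolerance in Da.
#' @param max_charge maximum fragment charge considered.
#' @return one-row data frame: `peptide`, `pearson_r`, `rt_endogenous_min`,
#'   `rt_synthetic_min`, `n_matched_fragments` (fragments with signal in
#'   both spectra) and logical `decision`.
#' @export
validate_pair <- function(endogenous, synthetic, peptide, r_min = 0.9,
                          rt_window_min = 3.0, rt_rule_enabled = FALSE,
                          tol_da = 0.02, max_charge = 1L) {
  frags <- theoretical_fragments(peptide, max_charge = max_charge)
  vecs <- match_intensity_vectors(endogenous, synthetic, frags,
                                  tol_da = tol_da)
  r <- mirror_pearson(vecs$a, vecs$b)
  d_rt <- abs(endogenous$rt_min - synthetic$rt_min)
  decision <- r >= r_min && (!rt_rule_enabled || d_rt <= rt_window_min)
  data.frame(peptide = peptide,
             pearson_r = r,
             rt_endogenous_min = endogenous$rt_min,
             rt_synthetic_min = synthetic$rt_min,
             n_matched_fragments = sum(vecs$a > 0 & vecs$b > 0),
             decision = decision,
             stringsAsFactors = FALSE)
}

#' Signed intensity columns for a mirror plot
#'
#' @inheritParams validate_pair
#' @return data frame with one row per theoretical fragment: `label`, `mz`,
#'   `intensity_up` (endogenous) and `intensity_down` (synthetic, negated).
#' @export
mirror_plot_data <- function(endogenous, synthetic, peptide, tol_da = 0.02,
                             max_charge = 1L) {
  frags <- theoretical_fragments(peptide, max_charge = max_charge)
  vecs <- match_intensity_vectors(endogenous, synthetic, frags,
                                  tol_da = tol_da)
  data.frame(label = frags$label, mz = frags$mz,
             intensity_up = vecs$a, intensity_down = -vecs$b,
             stringsAsFactors = FALSE)
}
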