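# Perseus-style label-free quantification differential expression:
# log2 transform and valid-value filtering, downshifted-normal imputation of
# missing-not-at-random values, two-sample t-tests with BH correction, and
# the Z-score / volcano export tables.

#' Log2-transform and valid-value-filter an LFQ matrix
#'
#' Retains proteins with at least `min_valid` observed values in at least
#' one group.  Groups with fewer than `min_valid` samples cannot satisfy
#' the rule and are skipped with a warning.  Idempotent: an already-log2
#' matrix is only re-filtered.
#'
#' @param lfq [lfq_matrix()].
#' @param min_valid minimum observed values per group (default 3).
#' @return filtered `lfq_matrix` on the log2 scale.
#' @export
preprocess_lfq <- function(lfq, min_valid = 3L) {
  values <- lfq$values
  if (!lfq$log2) values <- log2(values)
  groups <- lfq$groups
  usable <- names(which(table(groups) >= min_valid))
  if (length(usable) < length(unique(groups))) {
    warning("group(s) with fewer than ", min_valid,
            " samples cannot satisfy the valid-value rule: ",
            paste(setdiff(unique(groups), usable), collapse = ", "))
  }
  if (length(usable) == 0L) ip_stop("no group can satisfy the rule")
  keep <- apply(values, 1L, function(v) {
    any(vapply(usable, function(g) {
      sum(!is.na(v[groups == g])) >= min_valid
    }, logical(1)))
  })
  lfq_matrix(values[keep, , drop = FALSE], groups, log2 = TRUE)
}

#' Impute missing values from a downshifted normal distribution
#'
#' Per sample, missing entries are drawn from
#' `Normal(mean_s - downshift * sd_s, (width * sd_s)^2)` where `mean_s` and
#' `sd_s` are that sample's observed mean and SD — the standard treatment
#' of left-censored (low-abundance) missingness.  Observed cells are never
#' altered.
#'
#' @param lfq log2-scale [lfq_matrix()].
#' @param width imputation SD as a fraction of the sample SD (default 0.3).
#' @param downshift centre shift in sample SDs (default 1.8).
#' @param seed RNG seed.
#' @return complete `lfq_matrix`.
#' @export
impute_lfq <- function(lfq, width = 0.3, downshift = 1.8, seed) {
  if (!lfq$log2) ip_stop("impute_lfq expects a log2-scale matrix",
                         class = "immunopept_precondition_error")
  if (width <= 0) ip_stop("width must be > 0")
  values <- lfq$values
  ip_with_seed(seed, {
    for (j in seq_len(ncol(values))) {
      obs <- values[, j][!is.na(values[, j])]
      miss <- which(is.na(values[, j]))
      if (length(miss) == 0L) next
      if (length(obs) < 2L) {
        ip_stop("sample ", colnames(values)[j],
                " has fewer than 2 observed values",
                class = "immunopept_precondition_error")
      }
      m <- mean(obs)
      s <- stats::sd(obs)
      values[miss, j] <- stats::rnorm(length(miss), m - downshift * s,
                                      width * s)
    }
    lfq_matrix(values, lfq$groups, log2 = TRUE)
  })
}

#' Two-group differential expression test
#'
#' Two-sided two-sample t-test per protein (Student pooled-variance by
#' default, Welch optionally), Benjamini-Hochberg adjustment across
#' retained proteins, and an up/down/ns status call from the fold-change
#' and adjusted-p cutoffs.  The log2 fold change is group1 minus group2,
#' group order following first appearance in the sample layout.  Proteins
#' with zero variance in both groups get `p = 1` when the means are equal
#' (and `p = 0` otherwise, the degenerate limit).
#'
#' @param lfq complete log2-scale [lfq_matrix()] with exactly two groups of
#'   >= 2 samples each.
#' @param fc_cutoff absolute log2 fold-change cutoff for the status call
#'   (default 1).
#' @param alpha adjusted-p cutoff for the status call (default 0.05).
#' @param var_equal pooled-variance Student t (default `TRUE`); `FALSE`
#'   gives Welch.
#' @return data frame `protein`, `mean_<group1>`, `mean_<group2>`,
#'   `log2_fc`, `t`, `p`, `p_adj`, `status`.
#' @export
differential_test <- function(lfq, fc_cutoff = 1, alpha = 0.05,
                              var_equal = TRUE) {
  groups <- lfq$groups
  glev <- unique(unname(groups))
  if (length(glev) != 2L) ip_stop("exactly two groups are required")
  i1 <- which(groups == glev[1])
  i2 <- which(groups == glev[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    ip_stop("each group needs at least 2 samples")
  }
  values <- lfq$values
  if (anyNA(values)) ip_stop("matrix contains missing values: impute first",
                             class = "immunopept_precondition_error")
  n1 <- length(i1)
  n2 <- length(i2)
  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  v1 <- apply(values[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(values[, i2, drop = FALSE], 1L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  delta <- m1 - m2
  tstat <- ifelse(se == 0, ifelse(delta == 0, 0, Inf * sign(delta)),
                  delta / se)
  p <- ifelse(se == 0, ifelse(delta == 0, 1, 0),
              2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  p_adj <- stats::p.adjust(p, method = "BH")
  status <- ifelse(p_adj <= alpha & delta >= fc_cutoff, "up",
                   ifelse(p_adj <= alpha & delta <= -fc_cutoff, "down",
                          "ns"))
  out <- data.frame(protein = rownames(values), m1, m2,
                    log2_fc = delta, t = tstat, p = p, p_adj = p_adj,
                    status = status, stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", glev)
  rownames(out) <- NULL
  out
}

#' Row Z-scores with the sample (n-1) standard deviation
#'
#' Zero-variance rows become all-zero rather than `NaN`.
#'
#' @param mat numeric matrix.
#' @export
zscore_rows <- function(mat) {
  m <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  z <- (mat - m) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Volcano-plot table from differential expression results
#'
#' @param results output of [differential_test()].
#' @return data frame `protein`, `log2_fc`, `neg_log10_p`,
#'   `neg_log10_p_adj`, `status`.
#' @export
volcano_table <- function(results) {
  data.frame(protein = results$protein,
             log2_fc = results$log2_fc,
             neg_log10_p = -log10(results$p),
             neg_log10_p_adj = -log10(results$p_adj),
             status = results$status,
             stringsAsFactors = FALSE)
}
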