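# Length distributions, position-frequency motif analysis with logo-style
# enrichment statistics, and percent-rank based HLA restriction assignment.

#' Length distribution of a filtered peptide set
#'
#' @param peptides character vector; every peptide must fall inside
#'   `lengths` (run the filter ladder first).
#' @param lengths length range tallied (default 8:12).
#' @return data frame `length`, `count`, `fraction` (fractions sum to 1;
#'   `NA` fractions for an empty input).
#' @export
length_distribution <- function(peptides, lengths = 8:12) {
  n <- nchar(peptides)
  if (length(n) > 0L && any(!n %in% lengths)) {
    ip_stop("peptide length outside ", min(lengths), "-", max(lengths),
            ": run the filter ladder first",
            class = "immunopept_precondition_error")
  }
  counts <- vapply(lengths, function(L) sum(n == L), integer(1))
  data.frame(length = lengths, count = counts,
             fraction = if (sum(counts) > 0L) counts / sum(counts)
                        else rep(NA_real_, length(lengths)))
}

#' Position frequency matrix of equal-length peptides
#'
#' @param peptides character vector, all the same length.
#' @param pseudocount added to every cell count before normalisation
#'   (smoothed frequency `(count + pc) / (n + 20 pc)`); default 0.
#' @return 20 x L column-stochastic matrix, rows named by amino acid,
#'   columns `P1..PL`.
#' @export
build_pfm <- function(peptides, pseudocount = 0) {
  if (length(peptides) == 0L) ip_stop("no peptides")
  if (pseudocount < 0) ip_stop("pseudocount must be >= 0")
  L <- unique(nchar(peptides))
  if (length(L) != 1L) {
    ip_stop("mixed peptide lengths: build one matrix per length",
            class = "immunopept_precondition_error")
  }
  n <- length(peptides)
  mat <- matrix(pseudocount, nrow = 20L, ncol = L,
                dimnames = list(IP_AA, paste0("P", seq_len(L))))
  chars <- matrix(unlist(strsplit(peptides, "")), nrow = n, byrow = TRUE)
  for (pos in seq_len(L)) {
    tab <- table(factor(chars[, pos], levels = IP_AA))
    mat[, pos] <- mat[, pos] + as.integer(tab)
  }
  mat / (n + 20 * pseudocount)
}

#' Logo-style positional enrichment of an observed motif against a reference
#'
#' Scores every (position, residue) cell by the percentage-point difference
#' between observed and reference frequency and tests the observed count
#' against the reference frequency with an exact two-sided binomial test,
#' Bonferroni-corrected across all cells.  The `significant` matrix flags
#' cells passing the corrected test regardless of direction; `enriched`
#' marks the positive-difference side (the upper panel of a sequence logo),
#' which is the set used to assess anchor recovery.
#'
#' @param observed_pfm,reference_pfm equal-dimension frequency matrices
#'   (see [build_pfm()]).
#' @param n_observed number of peptides behind `observed_pfm`.
#' @param alpha familywise significance level (default 0.05).
#' @return object of class `motif_diff`: matrices `diff_pct`, `p_value`,
#'   `p_adj`, `significant`, `enriched`, plus `alpha` and `n_observed`.
#' @export
icelogo_diff <- function(observed_pfm, reference_pfm, n_observed,
                         alpha = 0.05) {
  if (!all(dim(observed_pfm) == dim(reference_pfm))) {
    ip_stop("observed and reference matrices must have identical dimensions",
            class = "immunopept_precondition_error")
  }
  if (n_observed < 1L) ip_stop("n_observed must be >= 1")
  counts <- round(observed_pfm * n_observed)
  p <- matrix(NA_real_, nrow(observed_pfm), ncol(observed_pfm),
              dimnames = dimnames(observed_pfm))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      ref <- min(max(reference_pfm[i, j], 0), 1)
      p[i, j] <- stats::binom.test(counts[i, j], n_observed, ref,
                                   alternative = "two.sided")$p.value
    }
  }
  p_adj <- p
  p_adj[] <- pmin(1, p * length(p))
  diff_pct <- (observed_pfm - reference_pfm) * 100
  structure(list(diff_pct = diff_pct, p_value = p, p_adj = p_adj,
                 significant = p_adj <= alpha,
                 enriched = p_adj <= alpha & diff_pct > 0,
                 alpha = alpha, n_observed = n_observed),
            class = "motif_diff")
}

#' Classify a percent rank into strong / weak / non-binder
#'
#' Strong binders have rank <= 0.5, weak binders 0.5 < rank <= 2.0, the
#' rest are non-binders (`SB`/`WB`/`NB`).  The boundaries belong to the
#' stronger class (rank 0.5 is SB, rank 2.0 is WB), following the predictor
#' convention that "rank <= 0.5" defines strong binding.
#'
#' @param percent_rank numeric vector of non-negative percent ranks.
#' @param sb_max,wb_max class boundaries (defaults 0.5 and 2.0).
#' @return factor with levels `SB`, `WB`, `NB`.
#' @export
categorize_rank <- function(percent_rank, sb_max = 0.5, wb_max = 2.0) {
  if (any(is.na(percent_rank)) || any(percent_rank < 0)) {
    ip_stop("percent rank must be non-negative",
            class = "immunopept_precondition_error")
  }
  factor(ifelse(percent_rank <= sb_max, "SB",
                ifelse(percent_rank <= wb_max, "WB", "NB")),
         levels = c("SB", "WB", "NB"))
}

#' Assign HLA restriction from per-allele percent ranks
#'
#' The allele with the minimum percent rank wins, with ties broken by
#' allele-name lexicographic order so the result is deterministic and
#' invariant to input ordering.  A peptide whose best rank is still a
#' non-binder is returned unassigned.
#'
#' @param ranks named numeric vector, `allele -> percent rank`; must be
#'   non-empty.
#' @param sb_only when `TRUE` only strong binders are assigned.
#' @inheritParams categorize_rank
#' @return list: `allele` (`NA` when unassigned), `percent_rank` and
#'   `category` (`"SB"`, `"WB"` or `"unassigned"`).
#' @export
assign_restriction <- function(ranks, sb_only = FALSE, sb_max = 0.5,
                               wb_max = 2.0) {
  if (length(ranks) == 0L || is.null(names(ranks))) {
    ip_stop("ranks must be a non-empty named vector",
            class = "immunopept_precondition_error")
  }
  ord <- order(ranks, names(ranks))
  best_allele <- names(ranks)[ord[1]]
  best_rank <- unname(ranks[ord[1]])
  cat_best <- as.character(categorize_rank(best_rank, sb_max, wb_max))
  if (cat_best == "NB" || (sb_only && cat_best != "SB")) {
    return(list(allele = NA_character_, percent_rank = best_rank,
                category = "unassigned"))
  }
  list(allele = best_allele, percent_rank = best_rank, category = cat_best)
}

#' Restriction table for a peptide set
#'
#' Applies [assign_restriction()] to every peptide of a rank table.
#'
#' @param ranks data frame `peptide`, `allele`, `percent_rank` (see
#'   [parse_rank_table()]).
#' @inheritParams assign_restriction
#' @return data frame `peptide`, `allele`, `percent_rank`, `category`.
#' @export
assign_restriction_table <- function(ranks, sb_only = FALSE, sb_max = 0.5,
                                     wb_max = 2.0) {
  out <- do.call(rbind, lapply(split(ranks, ranks$peptide), function(d) {
    r <- assign_restriction(stats::setNames(d$percent_rank, d$allele),
                            sb_only = sb_only, sb_max = sb_max,
                            wb_max = wb_max)
    data.frame(peptide = d$peptide[1], allele = r$allele,
               percent_rank = r$percent_rank, category = r$category,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$peptide, unique(ranks$peptide))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PSSM-based percent-rank surrogate
#'
#' An in-package stand-in for an external binding predictor: peptides are
#' scored by log-odds against a position frequency model and ranked as the
#' percentile of their score within a random-peptide background (lower
#' rank = stronger), mirroring how percent ranks are defined.
#'
#' @param peptides query peptides (same length as the model).
#' @param pfm position frequency matrix (see [build_pfm()]); zero cells are
#'   floored at 1e-4 before taking log-odds.
#' @param n_background background size (default 10000).
#' @param seed RNG seed for the background draw.
#' @return numeric percent ranks in (0, 100\].
#' @export
pssm_percent_rank <- function(peptides, pfm, n_background = 10000L, seed) {
  L <- ncol(pfm)
  if (any(nchar(peptides) != L)) {
    ip_stop("peptides must match the model length ", L)
  }
  lo <- log(pmax(pfm, 1e-4) / (1 / 20))
  score1 <- function(p) {
    ri <- match(strsplit(p, "")[[1]], rownames(lo))
    sum(lo[cbind(ri, seq_len(L))])
  }
  bg <- ip_with_seed(seed, ip_random_peptides(n_background, L))
  bg_scores <- sort(vapply(bg, score1, numeric(1)))
  vapply(peptides, function(p) {
    s <- score1(p)
    # fraction of background scoring at least as well
    100 * (1 - (findInterval(s, bg_scores, left.open = TRUE) /
                  n_background)) },
    numeric(1), USE.NAMES = FALSE)
}
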