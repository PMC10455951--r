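# Cross-referencing of the retained immunopeptidome against annotation
# databases, exclusive set-intersection (UpSet) counting, conserved-peptide
# heatmap input, and hypergeometric term enrichment.

#' Annotate retained peptides against reference databases
#'
#' Peptide-level databases match on exact sequence; protein-level databases
#' match when *any* source protein of the peptide is a member (so a
#' multi-mapping peptide inherits the flag from any of its proteins).
#'
#' @param entries retained-peptide table (needs `sequence` and
#'   semicolon-joined `proteins`).
#' @param databases list of [annotation_db()] objects.
#' @return `entries` with one logical flag column per database (named after
#'   the database) plus attributes `overlap_counts` (flagged peptides per
#'   database) and `n_multi_flagged` (peptides carrying >= 2 flags).
#' @export
annotate <- function(entries, databases) {
  prot_lists <- strsplit(entries$proteins, ";", fixed = TRUE)
  flags <- matrix(FALSE, nrow(entries), length(databases))
  nm <- character(length(databases))
  for (k in seq_along(databases)) {
    db <- databases[[k]]
    if (!inherits(db, "annotation_db")) {
      ip_stop("databases must be annotation_db objects")
    }
    nm[k] <- db$name
    flags[, k] <- if (db$kind == "peptide") {
      entries$sequence %in% db$members
    } else {
      vapply(prot_lists, function(p) any(p %in% db$members), logical(1))
    }
  }
  colnames(flags) <- nm
  out <- cbind(entries, as.data.frame(flags))
  attr(out, "overlap_counts") <- colSums(flags)
  attr(out, "n_multi_flagged") <- if (length(databases) > 0L) {
    sum(rowSums(flags) >= 2L)
  } else 0L
  out
}

#' Exclusive intersection counts over a family of sets (UpSet counts)
#'
#' Every member of the union is counted in exactly one of the 2^k - 1
#' combinations, so the counts sum to the union cardinality.
#'
#' @param sets named list of 1 to 12 character vectors.
#' @return data frame with one row per combination: `combo`
#'   (ampersand-joined set names), `degree` and `count` (zero-count
#'   combinations included).
#' @export
set_intersections <- function(sets) {
  k <- length(sets)
  if (k == 0L) ip_stop("at least one set is required",
                       class = "immunopept_precondition_error")
  if (k > 12L) ip_stop("at most 12 sets are supported")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_len(k))
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, names(sets)))
  # encode each member's membership pattern as an integer
  code <- as.integer(membership %*% 2^(seq_len(k) - 1))
  all_codes <- seq_len(2^k - 1L)
  tallied <- tabulate(code, nbins = 2^k - 1L)
  combo_name <- vapply(all_codes, function(cd) {
    paste(names(sets)[bitwAnd(cd, 2^(seq_len(k) - 1)) > 0], collapse = "&")
  }, character(1))
  data.frame(combo = combo_name,
             degree = vapply(all_codes, function(cd) {
               sum(bitwAnd(cd, 2^(seq_len(k) - 1)) > 0)
             }, integer(1)),
             count = tallied,
             stringsAsFactors = FALSE)
}

#' Row-standardised intensity matrix of the top shared peptides
#'
#' Keeps the rows observed in every sample, orders them by descending mean
#' log2 intensity, takes the top `k` and Z-scores each row with the sample
#' (n-1) standard deviation; zero-variance rows become all-zero.
#'
#' @param mat numeric matrix of log2 intensities, peptides x samples (`NA`
#'   = not observed in that sample).
#' @param k number of top rows (default 40); when fewer rows are fully
#'   shared, all of them are returned with a warning.
#' @return Z-scored matrix with a `mean_log2` attribute carrying the
#'   pre-scaling row means.
#' @export
top_shared_matrix <- function(mat, k = 40L) {
  shared <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(shared) < k) {
    warning(sprintf("only %d fully shared peptides (requested %d)",
                    nrow(shared), k))
    k <- nrow(shared)
  }
  means <- rowMeans(shared)
  top <- shared[order(-means)[seq_len(k)], , drop = FALSE]
  z <- zscore_rows(top)
  attr(z, "mean_log2") <- rowMeans(top)
  z
}

#' Right-sided hypergeometric term enrichment with familywise correction
#'
#' For each term, tests whether the query set over-represents the term's
#' members relative to the background: `p = P(X >= x)` with `X`
#' hypergeometric(`N` = background size, `K` = term members in background,
#' `n` = query size).  Terms with no background members are skipped with a
#' warning.  The default correction is plain Bonferroni
#' (`min(1, p * n_terms)`); Holm is available.
#'
#' @param query protein set; must be a subset of `background`.
#' @param terms named list of term -> member character vectors.
#' @param background background protein universe.
#' @param correction `"bonferroni"` (default) or `"holm"`.
#' @return data frame `term`, `hits`, `term_size`, `query_size`, `p`,
#'   `p_adj`, ordered by `p`.
#' @export
enrich_terms <- function(query, terms, background,
                         correction = c("bonferroni", "holm")) {
  correction <- match.arg(correction)
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background)) {
    ip_stop("query must be a subset of the background",
            class = "immunopept_precondition_error")
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(terms), function(tn) {
    members <- intersect(terms[[tn]], background)
    K <- length(members)
    if (K == 0L) {
      warning(sprintf("term '%s' has no background members; skipped", tn))
      return(NULL)
    }
    x <- length(intersect(query, members))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tn, hits = x, term_size = K, query_size = n, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), hits = integer(0),
                      term_size = integer(0), query_size = integer(0),
                      p = numeric(0), p_adj = numeric(0)))
  }
  out$p_adj <- stats::p.adjust(out$p, method = correction)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
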