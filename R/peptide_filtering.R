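# The data-processing ladder that turns raw PSM tables into the
# non-redundant 8-12-mer immunopeptidome: target-decoy q-value estimation,
# FDR cutoff, removal of decoys / spiked calibrants / blank-run carryover /
# modified peptides, length restriction, and sequence-level deduplication.

#' Filtering configuration
#'
#' @param fdr_cutoff q-value cutoff (default 0.05).
#' @param length_min,length_max retained peptide length range (default 8-12).
#' @param drop_modified drop PSMs carrying any modification (default TRUE).
#' @param blank_peptides sequences detected in blank runs.
#' @param irt_peptides spiked retention-time calibrant sequences (defaults
#'   to the package's calibrant list).
#' @export
filter_config <- function(fdr_cutoff = 0.05, length_min = 8L,
                          length_max = 12L, drop_modified = TRUE,
                          blank_peptides = character(0),
                          irt_peptides = IP_IRT_PEPTIDES) {
  if (fdr_cutoff <= 0 || fdr_cutoff > 1) {
    ip_stop("fdr_cutoff must be in (0, 1]")
  }
  if (length_min > length_max) ip_stop("length_min must be <= length_max")
  structure(list(fdr_cutoff = fdr_cutoff,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 drop_modified = isTRUE(drop_modified),
                 blank_peptides = unique(blank_peptides),
                 irt_peptides = unique(irt_peptides)),
            class = "filter_config")
}

#' Target-decoy q-values for PSM scores
#'
#' At a score threshold s the FDR estimate is
#' `#\{decoys >= s\} / max(1, #\{targets >= s\})`; q-values are the
#' monotonized (running-minimum from the bottom of the score ranking)
#' FDR, clipped to at most 1.  q is non-increasing in score and invariant
#' under monotone score transforms.
#'
#' @param scores numeric PSM scores (higher = better).
#' @param is_decoy logical decoy flags; at least one target and one decoy
#'   are required.
#' @return numeric q-values in input order.
#' @export
estimate_q_values <- function(scores, is_decoy) {
  if (length(scores) != length(is_decoy)) {
    ip_stop("scores and is_decoy must have equal length")
  }
  if (!any(is_decoy)) {
    ip_stop("no decoys among inputs: q-values are not estimable",
            class = "immunopept_precondition_error")
  }
  if (all(is_decoy)) {
    ip_stop("all-decoy input: q-values are not estimable",
            class = "immunopept_precondition_error")
  }
  ord <- order(scores, decreasing = TRUE)
  dec <- is_decoy[ord]
  n_dec <- cumsum(dec)
  n_tgt <- cumsum(!dec)
  # at a threshold equal to score s, every PSM tied at s counts, so
  # evaluate the running totals at the last row of each tie group
  s <- scores[ord]
  runs <- rle(s)$lengths
  grp_last <- cumsum(runs)
  idx <- rep(grp_last, runs)
  fdr <- n_dec[idx] / pmax(1, n_tgt[idx])
  q <- rev(cummin(rev(fdr)))
  q <- pmin(q, 1)
  out <- numeric(length(scores))
  out[ord] <- q
  out
}

#' Apply the fixed-order peptide filtering ladder
#'
#' Steps, in order: (1) keep q <= `fdr_cutoff` (q-values are estimated via
#' [estimate_q_values()] when absent); (2) drop decoys; (3) drop calibrant
#' sequences; (4) drop sequences detected in blanks; (5) drop modified
#' PSMs; (6) keep lengths within the configured range; (7) deduplicate by
#' bare sequence keeping the highest-scoring PSM and merging per-sample
#' maximum intensities.  The retained *set* is order-invariant; only the
#' per-step removal counts depend on this order.
#'
#' @param psms canonical PSM data frame (see [parse_psm_table()]).
#' @param config a [filter_config()].
#' @return object of class `filter_report`: `counts` (input, per-step
#'   removals, retained — removals always sum to input minus retained),
#'   `retained` (non-redundant peptide table with `sequence`, `score`,
#'   `proteins`, `n_psms` and one `intensity.<sample>` column per sample),
#'   and `per_sample_counts` (unique retained sequences per sample).
#' @export
apply_filter_ladder <- function(psms, config = filter_config()) {
  steps <- c("fdr", "decoy", "irt", "blank", "modified", "length",
             "duplicate")
  counts <- stats::setNames(integer(length(steps)), steps)
  n_input <- nrow(psms)
  if (n_input == 0L) {
    return(structure(list(
      counts = c(input = 0L, counts, retained = 0L),
      retained = data.frame(sequence = character(0), score = numeric(0),
                            proteins = character(0), n_psms = integer(0)),
      per_sample_counts = integer(0)), class = "filter_report"))
  }
  q <- psms$q_value
  if (all(is.na(q))) {
    q <- estimate_q_values(psms$score, psms$is_decoy)
  } else if (anyNA(q)) {
    ip_stop("q_value partially missing: supply all or none")
  }
  keep <- rep(TRUE, n_input)
  drop_step <- function(bad, step) {
    bad <- bad & keep
    counts[[step]] <<- sum(bad)
    keep[bad] <<- FALSE
  }
  drop_step(q > config$fdr_cutoff, "fdr")
  drop_step(psms$is_decoy, "decoy")
  drop_step(psms$sequence %in% config$irt_peptides, "irt")
  drop_step(psms$sequence %in% config$blank_peptides, "blank")
  if (config$drop_modified) {
    drop_step(nzchar(psms$modifications), "modified")
  }
  len <- nchar(psms$sequence)
  drop_step(len < config$length_min | len > config$length_max, "length")

  surv <- psms[keep, , drop = FALSE]
  samples <- sort(unique(psms$sample))
  retained <- data.frame(sequence = character(0), score = numeric(0),
                         proteins = character(0), n_psms = integer(0))
  if (nrow(surv) > 0L) {
    # highest-score PSM per sequence; first occurrence wins ties
    ord <- order(-surv$score, seq_len(nrow(surv)))
    best <- surv[ord, ][!duplicated(surv$sequence[ord]), , drop = FALSE]
    best <- best[order(match(best$sequence, surv$sequence)), , drop = FALSE]
    counts[["duplicate"]] <- nrow(surv) - nrow(best)
    split_prot <- function(p) unlist(strsplit(p, ";", fixed = TRUE))
    retained <- data.frame(
      sequence = best$sequence,
      score = best$score,
      proteins = vapply(best$sequence, function(sq) {
        paste(sort(unique(split_prot(
          surv$proteins[surv$sequence == sq]))), collapse = ";")
      }, character(1)),
      n_psms = as.integer(table(surv$sequence)[best$sequence]),
      stringsAsFactors = FALSE
    )
    for (smp in samples) {
      retained[[paste0("intensity.", smp)]] <- vapply(
        best$sequence, function(sq) {
          v <- surv$intensity[surv$sequence == sq & surv$sample == smp]
          if (all(is.na(v)) || length(v) == 0L) NA_real_ else max(v, na.rm = TRUE)
        }, numeric(1))
    }
    rownames(retained) <- NULL
  }
  per_sample <- vapply(samples, function(smp) {
    length(unique(surv$sequence[surv$sample == smp]))
  }, integer(1))
  structure(list(counts = c(input = n_input, counts,
                            retained = nrow(retained)),
                 retained = retained,
                 per_sample_counts = per_sample),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Peptide filter report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-10s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Write a filter report to tab-separated files
#'
#' @param report `filter_report`.
#' @param summary_path,retained_path output paths.
#' @export
write_filter_report <- function(report, summary_path, retained_path) {
  utils::write.table(
    data.frame(step = names(report$counts), count = unname(report$counts)),
    summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$retained, retained_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(report)
}

#' Peptides-per-protein tally
#'
#' A peptide mapping to several proteins counts once for each of them.
#'
#' @param retained retained-peptide table from [apply_filter_ladder()]
#'   (needs `sequence` and semicolon-joined `proteins`).
#' @return list: `counts` (named integer, peptides per protein) and
#'   `singleton_fraction` (fraction of source proteins contributing exactly
#'   one peptide).
#' @export
peptides_per_protein <- function(retained) {
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(retained)), function(i) {
    prots <- unlist(strsplit(retained$proteins[i], ";", fixed = TRUE))
    prots <- prots[nzchar(prots)]
    if (length(prots) == 0L) return(NULL)
    data.frame(sequence = retained$sequence[i], protein = prots,
               stringsAsFactors = FALSE)
  })))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(counts = stats::setNames(integer(0), character(0)),
                singleton_fraction = NA_real_))
  }
  counts <- table(pairs$protein)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       singleton_fraction = mean(counts == 1L))
}
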