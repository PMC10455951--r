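# Cell-surface proteome analysis: the shared detection core across cell
# lines, transmembrane-helix filtering, and intensity ranking with
# surface-marker annotation.

#' Proteins shared by every cell line
#'
#' @param sets list (>= 1) of per-line protein accession vectors.
#' @return character vector, the exact intersection.
#' @export
shared_core <- function(sets) {
  if (length(sets) == 0L) ip_stop("at least one set is required",
                                  class = "immunopept_precondition_error")
  Reduce(intersect, lapply(sets, unique))
}

#' Filter proteins by predicted transmembrane helix count
#'
#' Retains proteins whose predicted helix count is at least `min_helices`
#' (default 3, the conventional multi-pass membrane protein cutoff).
#'
#' @param proteins accessions to filter.
#' @param tm_predictions data frame `protein`, `pred_hel` (see
#'   [parse_tm_table()]).
#' @param min_helices retention threshold (default 3).
#' @param missing what to do with proteins lacking a prediction:
#'   `"error"` (default) or `"drop"`.
#' @return character vector of retained proteins, in input order.
#' @export
tm_filter <- function(proteins, tm_predictions, min_helices = 3L,
                      missing = c("error", "drop")) {
  missing <- match.arg(missing)
  hel <- tm_predictions$pred_hel[match(proteins, tm_predictions$protein)]
  if (anyNA(hel)) {
    if (missing == "error") {
      ip_stop("no TM prediction for: ",
              paste(utils::head(proteins[is.na(hel)], 5L), collapse = ", "),
              class = "immunopept_precondition_error")
    }
    proteins <- proteins[!is.na(hel)]
    hel <- hel[!is.na(hel)]
  }
  proteins[hel >= min_helices]
}

#' Rank shared surface proteins by mean log intensity
#'
#' Orders the shared proteins by descending mean log2 LFQ intensity across
#' cell lines (accession lexicographic order breaks ties) and attaches the
#' surface-marker annotation: membership of a curated surface-protein
#' database, CD-marker naming (`CD` + digits) and solute-carrier family
#' naming (`SLC` prefix).
#'
#' @param proteins shared protein accessions.
#' @param lfq [lfq_matrix()] of protein intensities (log2-transformed
#'   internally when raw).
#' @param k number of top proteins (default 50); when `k` exceeds the
#'   number of shared proteins all are returned with a warning.
#' @param cspa optional [annotation_db()] (protein kind) of curated surface
#'   proteins.
#' @param gene_symbols optional named map accession -> gene symbol used for
#'   the CD / SLC name rules (accessions themselves are used when absent).
#' @return data frame `protein`, `gene_symbol`, `mean_log2_intensity`,
#'   `cspa`, `cd_marker`, `slc_family`, ordered by rank.
#' @export
rank_surface <- function(proteins, lfq, k = 50L, cspa = NULL,
                         gene_symbols = NULL) {
  values <- lfq$values
  if (!lfq$log2) values <- log2(values)
  missing_rows <- setdiff(proteins, rownames(values))
  if (length(missing_rows) > 0L) {
    ip_stop("no intensities for: ",
            paste(utils::head(missing_rows, 5L), collapse = ", "))
  }
  if (k > length(proteins)) {
    warning(sprintf("k = %d exceeds the %d shared proteins; returning all",
                    k, length(proteins)))
    k <- length(proteins)
  }
  mean_int <- rowMeans(values[proteins, , drop = FALSE], na.rm = TRUE)
  ord <- order(-mean_int, proteins)
  top <- proteins[ord][seq_len(k)]
  sym <- if (is.null(gene_symbols)) {
    stats::setNames(top, top)
  } else {
    out <- gene_symbols[top]
    out[is.na(out)] <- top[is.na(out)]
    stats::setNames(out, top)
  }
  data.frame(
    protein = top,
    gene_symbol = unname(sym),
    mean_log2_intensity = unname(mean_int[top]),
    cspa = if (is.null(cspa)) FALSE else top %in% cspa$members,
    cd_marker = grepl("^CD[0-9]", unname(sym)),
    slc_family = grepl("^SLC", unname(sym)),
    stringsAsFactors = FALSE
  )
}
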