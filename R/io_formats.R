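# Readers and writers for the external formats the pipeline touches:
# tab-separated PSM / binding-rank / LFQ / transmembrane tables, MGF spectra,
# FASTA proteomes and plain-text annotation lists.  The canonical in-house
# dialects round-trip bit-faithfully; foreign dialects map in through the
# `dialect` argument (a named character vector canonical -> file column).

IP_PSM_COLUMNS <- c("sequence", "modifications", "score", "q_value",
                    "is_decoy", "sample", "antibody", "rt_min",
                    "intensity", "proteins")
IP_PSM_REQUIRED <- c("sequence", "score", "sample")

#' Parse a modification annotation string
#'
#' Modifications are encoded `"pos|Name"` and semicolon-joined, e.g.
#' `"4|Oxidation;7|Phospho"`.  The empty string (or `NA`) means unmodified.
#'
#' @param x character vector of modification strings.
#' @return list of data frames with columns `position` (1-based residue
#'   index) and `name`.
#' @export
parse_mod_string <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(position = integer(0), name = character(0),
                        stringsAsFactors = FALSE))
    }
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    ok <- grepl("^[0-9]+\\|[^;|]+$", toks)
    if (!all(ok)) {
      ip_stop("malformed modification token(s): ",
              paste(toks[!ok], collapse = ", "),
              class = "immunopept_format_error")
    }
    parts <- strsplit(toks, "|", fixed = TRUE)
    data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
               name = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
}

#' @rdname parse_mod_string
#' @param mods list of data frames as returned by [parse_mod_string()].
#' @export
format_mod_string <- function(mods) {
  vapply(mods, function(m) {
    if (nrow(m) == 0L) return("")
    paste(paste0(m$position, "|", m$name), collapse = ";")
  }, character(1))
}

#' Read a peptide-spectrum-match table
#'
#' Reads a tab-separated PSM table (one row per PSM) into the canonical
#' column layout.  Required columns are `sequence`, `score` and `sample`;
#' `modifications`, `q_value`, `is_decoy`, `antibody`, `rt_min`, `intensity`
#' and `proteins` (semicolon-joined accessions) are optional.  When no
#' explicit decoy column exists, decoy status is inferred from accessions
#' starting with `decoy_prefix`.
#'
#' @param path file path.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(sequence = "Peptide")`.
#' @param decoy_prefix accession prefix marking decoy entries.
#' @return data frame with the canonical PSM columns, one row per input row,
#'   in file order.
#' @export
parse_psm_table <- function(path, dialect = NULL, decoy_prefix = "DECOY_") {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), quote = "")
  cols <- names(raw)
  pick <- function(canonical) {
    file_col <- if (!is.null(dialect) && canonical %in% names(dialect)) {
      dialect[[canonical]]
    } else {
      canonical
    }
    if (file_col %in% cols) raw[[file_col]] else NULL
  }
  for (req in IP_PSM_REQUIRED) {
    if (is.null(pick(req))) {
      ip_stop("PSM table is missing required column: ", req,
              class = "immunopept_format_error")
    }
  }
  n <- nrow(raw)
  blank_chr <- rep(NA_character_, n)
  out <- data.frame(
    sequence = toupper(pick("sequence")),
    modifications = { m <- pick("modifications"); if (is.null(m)) rep("", n) else ifelse(is.na(m), "", m) },
    score = as.numeric(pick("score")),
    q_value = { q <- pick("q_value"); if (is.null(q)) rep(NA_real_, n) else as.numeric(q) },
    sample = pick("sample"),
    antibody = { a <- pick("antibody"); if (is.null(a)) blank_chr else a },
    rt_min = { r <- pick("rt_min"); if (is.null(r)) rep(NA_real_, n) else as.numeric(r) },
    intensity = { i <- pick("intensity"); if (is.null(i)) rep(NA_real_, n) else as.numeric(i) },
    proteins = { p <- pick("proteins"); if (is.null(p)) rep("", n) else ifelse(is.na(p), "", p) },
    stringsAsFactors = FALSE
  )
  dec <- pick("is_decoy")
  out$is_decoy <- if (!is.null(dec)) {
    toupper(dec) %in% c("TRUE", "T", "1", "YES")
  } else {
    vapply(strsplit(out$proteins, ";", fixed = TRUE), function(p) {
      any(startsWith(p, decoy_prefix))
    }, logical(1))
  }
  out <- out[, IP_PSM_COLUMNS]
  validate_psm_table(out)
  out
}

validate_psm_table <- function(psm) {
  bad_seq <- which(!ip_is_sequence(psm$sequence))
  if (length(bad_seq) > 0L) {
    ip_stop("invalid peptide sequence at row(s): ",
            paste(utils::head(bad_seq, 5L), collapse = ", "),
            class = "immunopept_format_error")
  }
  mods <- tryCatch(parse_mod_string(psm$modifications), error = function(e) e)
  if (inherits(mods, "error")) stop(mods)
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    if (nrow(m) > 0L &&
        (any(m$position < 1L) || any(m$position > nchar(psm$sequence[i])))) {
      ip_stop("modification position out of range at row ", i,
              class = "immunopept_format_error")
    }
  }
  qv <- psm$q_value[!is.na(psm$q_value)]
  if (any(qv < 0 | qv > 1)) {
    ip_stop("q_value outside [0, 1]", class = "immunopept_format_error")
  }
  invisible(psm)
}

#' @rdname parse_psm_table
#' @param psm canonical PSM data frame.
#' @export
write_psm_table <- function(psm, path) {
  utils::write.table(psm[, IP_PSM_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- spectra (MGF) ---------------------------------------------------------

#' Construct a fragment spectrum
#'
#' @param title spectrum title.
#' @param precursor_mz precursor m/z in Thomson.
#' @param precursor_charge positive integer charge.
#' @param rt_min retention time in minutes (the internal RT unit everywhere).
#' @param peaks two-column matrix (`mz`, `intensity`); rows are sorted
#'   ascending by m/z on construction.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(title, precursor_mz, precursor_charge, rt_min, peaks) {
  peaks <- matrix(as.numeric(peaks), ncol = 2L,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(peaks) > 0L) {
    if (any(peaks[, "mz"] <= 0)) {
      ip_stop("peak m/z must be strictly positive",
              class = "immunopept_format_error")
    }
    if (any(peaks[, "intensity"] < 0)) {
      ip_stop("peak intensity must be non-negative",
              class = "immunopept_format_error")
    }
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  }
  if (precursor_charge < 1L || precursor_charge != round(precursor_charge)) {
    ip_stop("precursor_charge must be a positive integer",
            class = "immunopept_format_error")
  }
  structure(list(title = as.character(title),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 rt_min = as.numeric(rt_min),
                 peaks = peaks),
            class = "spectrum")
}

#' Read an MGF file into a list of spectra
#'
#' Supports `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`
#' (`2+` or `2`), and retention time as either `RTINSECONDS` or
#' `RTINMINUTES`; retention times are converted to minutes.
#'
#' @param path MGF file path.
#' @return list of `spectrum` objects in file order (empty list for an empty
#'   file).
#' @export
parse_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  block <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) ip_stop("nested BEGIN IONS at line ", ln,
                            class = "immunopept_format_error")
      in_block <- TRUE
      block <- list(title = "", pepmass = NA_real_, charge = 1L,
                    rt_min = NA_real_, mz = numeric(0), int = numeric(0))
      next
    }
    if (line == "END IONS") {
      if (!in_block) ip_stop("END IONS without BEGIN IONS at line ", ln,
                             class = "immunopept_format_error")
      spectra[[length(spectra) + 1L]] <- spectrum(
        block$title, block$pepmass, block$charge, block$rt_min,
        cbind(block$mz, block$int))
      in_block <- FALSE
      next
    }
    if (!in_block) next
    if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") block$title <- val
      else if (key == "PEPMASS") block$pepmass <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
      else if (key == "CHARGE") block$charge <- as.integer(sub("[+-]$", "", val))
      else if (key == "RTINSECONDS") block$rt_min <- as.numeric(val) / 60
      else if (key == "RTINMINUTES") block$rt_min <- as.numeric(val)
      next
    }
    toks <- strsplit(line, "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      ip_stop("non-numeric peak line at line ", ln, ": ", line,
              class = "immunopept_format_error")
    }
    block$mz <- c(block$mz, vals[1])
    block$int <- c(block$int, vals[2])
  }
  if (in_block) {
    ip_stop("unterminated BEGIN IONS block at end of file",
            class = "immunopept_format_error")
  }
  spectra
}

#' @rdname parse_mgf
#' @param spectra list of `spectrum` objects.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$title),
                 paste0("PEPMASS=", format(s$precursor_mz, digits = 10)),
                 paste0("CHARGE=", s$precursor_charge, "+"),
                 paste0("RTINMINUTES=", format(s$rt_min, digits = 10)),
                 paste(format(s$peaks[, "mz"], digits = 10, trim = TRUE),
                       format(s$peaks[, "intensity"], digits = 10, trim = TRUE)),
                 "END IONS"), con)
  }
  invisible(path)
}

# ---- binding-rank tables ---------------------------------------------------

# Column aliases for NetMHCpan-style exports.
IP_RANK_ALIASES <- list(
  peptide = c("peptide", "Peptide"),
  allele = c("allele", "MHC", "HLA", "Allele"),
  percent_rank = c("percent_rank", "%Rank", "%Rank_EL", "Rank", "EL_Rank")
)

#' Read a per-peptide-per-allele percent-rank table
#'
#' Accepts the canonical `peptide`/`allele`/`percent_rank` header or
#' NetMHCpan-style column names (`Peptide`, `MHC`, `%Rank`).  Duplicate
#' (peptide, allele) rows collapse to the minimum rank.
#'
#' @inheritParams parse_psm_table
#' @return data frame with columns `peptide`, `allele`, `percent_rank`.
#' @export
parse_rank_table <- function(path, dialect = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  pick <- function(canonical) {
    cands <- if (!is.null(dialect) && canonical %in% names(dialect)) {
      dialect[[canonical]]
    } else {
      IP_RANK_ALIASES[[canonical]]
    }
    hit <- intersect(cands, names(raw))
    if (length(hit) == 0L) {
      ip_stop("rank table is missing column: ", canonical,
              class = "immunopept_format_error")
    }
    raw[[hit[1]]]
  }
  out <- data.frame(peptide = toupper(as.character(pick("peptide"))),
                    allele = as.character(pick("allele")),
                    percent_rank = as.numeric(pick("percent_rank")),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$percent_rank)) || any(out$percent_rank < 0)) {
    ip_stop("percent rank must be a non-negative number",
            class = "immunopept_format_error")
  }
  collapsed <- stats::aggregate(percent_rank ~ peptide + allele, data = out,
                                FUN = min)
  # preserve first-appearance order of (peptide, allele)
  key <- paste(out$peptide, out$allele, sep = "\r")
  ckey <- paste(collapsed$peptide, collapsed$allele, sep = "\r")
  collapsed <- collapsed[order(match(ckey, key)), , drop = FALSE]
  rownames(collapsed) <- NULL
  collapsed
}

#' @rdname parse_rank_table
#' @param ranks rank data frame.
#' @export
write_rank_table <- function(ranks, path) {
  utils::write.table(ranks[, c("peptide", "allele", "percent_rank")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- annotation lists, FASTA, TM tables ------------------------------------

#' Construct an annotation database
#'
#' @param name database label (e.g. `"IEDB"`, `"CSPA"`).
#' @param kind `"peptide"` (members are sequences, joined on exact sequence)
#'   or `"protein"` (members are accessions, joined on any source protein).
#' @param members character vector of members; must be non-empty.
#' @export
annotation_db <- function(name, kind = c("peptide", "protein"), members) {
  kind <- match.arg(kind)
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L) {
    ip_stop("annotation database '", name, "' has no members ",
            "(an empty reference database is a configuration mistake)",
            class = "immunopept_format_error")
  }
  structure(list(name = name, kind = kind, members = members),
            class = "annotation_db")
}

#' Read a one-member-per-line annotation list
#'
#' @param path plain-text file, one accession or peptide per line; blank
#'   lines and `#` comments are ignored; duplicates collapse (set semantics).
#' @inheritParams annotation_db
#' @export
parse_named_list <- function(path, name, kind = c("peptide", "protein")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  annotation_db(name, match.arg(kind), lines)
}

#' @rdname parse_named_list
#' @param db `annotation_db` object.
#' @export
write_named_list <- function(db, path) {
  writeLines(db$members, path)
  invisible(path)
}

#' Read a FASTA proteome into an accession -> sequence mapping
#'
#' UniProt-style headers (`>sp|P04637|P53_HUMAN ...`) are reduced to the
#' primary accession; other headers keep the first whitespace-delimited
#' token.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
parse_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  hdr <- names(aa)
  first <- vapply(strsplit(hdr, "[ \t]"), `[`, "", 1L)
  acc <- ifelse(grepl("^(sp|tr)\\|", first),
                vapply(strsplit(first, "|", fixed = TRUE), `[`, "", 2L),
                first)
  names(seqs) <- acc
  seqs
}

#' Read a TMHMM-style summary table of predicted transmembrane helix counts
#'
#' Each non-empty line names a protein in its first token and carries a
#' `PredHel=<n>` token (TMHMM short-format convention).
#'
#' @param path file path.
#' @return data frame with columns `protein` and `pred_hel`.
#' @export
parse_tm_table <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(protein = character(0), pred_hel = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(lines, regexpr("PredHel=[0-9]+", lines))
  if (length(m) != length(lines)) {
    ip_stop("line without a PredHel= token in TM table",
            class = "immunopept_format_error")
  }
  data.frame(
    protein = vapply(strsplit(lines, "[ \t]+"), `[`, "", 1L),
    pred_hel = as.integer(sub("PredHel=", "", m, fixed = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' @rdname parse_tm_table
#' @param tm data frame with `protein` and `pred_hel`.
#' @export
write_tm_table <- function(tm, path) {
  writeLines(sprintf("%s\tPredHel=%d", tm$protein, as.integer(tm$pred_hel)),
             path)
  invisible(path)
}

# ---- LFQ matrices ----------------------------------------------------------

#' Construct an LFQ protein-by-sample intensity matrix
#'
#' @param values numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample labels); `NA` marks missing.
#' @param groups named character vector mapping every sample to its group.
#' @param log2 whether `values` are already log2-transformed.  Pre-log
#'   intensities must be positive where present.
#' @return object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(values, groups, log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ip_stop("lfq_matrix requires protein rownames and sample colnames",
            class = "immunopept_format_error")
  }
  if (!all(colnames(values) %in% names(groups))) {
    ip_stop("every sample must have a group assignment",
            class = "immunopept_format_error")
  }
  if (!log2 && any(values[!is.na(values)] <= 0)) {
    ip_stop("pre-log intensities must be positive where present",
            class = "immunopept_format_error")
  }
  structure(list(values = values,
                 groups = groups[colnames(values)],
                 log2 = isTRUE(log2)),
            class = "lfq_matrix")
}

#' Read / write LFQ matrices
#'
#' Tab-separated layout: a `#groups:` comment line mapping samples to
#' groups (`sample=group`, comma-separated), a `#scale:` line (`raw` or
#' `log2`), then a header row (`protein` + sample labels) and one row per
#' protein.  Missing values are `NA`.
#'
#' @param path file path.
#' @export
read_lfq_matrix <- function(path) {
  lines <- readLines(path)
  gline <- grep("^#groups:", lines, value = TRUE)
  sline <- grep("^#scale:", lines, value = TRUE)
  if (length(gline) != 1L) {
    ip_stop("LFQ file is missing its #groups: header",
            class = "immunopept_format_error")
  }
  pairs <- strsplit(strsplit(sub("^#groups:", "", gline), ",")[[1]], "=")
  groups <- vapply(pairs, function(p) trimws(p[2]), character(1))
  names(groups) <- vapply(pairs, function(p) trimws(p[1]), character(1))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                           check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  lfq_matrix(values, groups,
             log2 = length(sline) == 1L && grepl("log2", sline))
}

#' @rdname read_lfq_matrix
#' @param lfq `lfq_matrix` object.
#' @export
write_lfq_matrix <- function(lfq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#groups:", paste(names(lfq$groups), lfq$groups, sep = "=",
                             collapse = ",")),
    paste0("#scale:", if (lfq$log2) "log2" else "raw")), con)
  tab <- data.frame(protein = rownames(lfq$values), lfq$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
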