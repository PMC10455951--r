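# End-to-end orchestration: one configuration drives the synthetic demo
# scenario through every stage and writes the artifact directory.  Each
# stage is an exported function in its own right; `run_pipeline()` wires
# them together deterministically under a single seed.

#' Default demo scenario configuration
#'
#' Parameters of the bundled synthetic end-to-end scenario: a motif-
#' structured HLA-A2-like repertoire with realistic contamination, a
#' two-group LFQ experiment with MNAR dropout, and a seven-line surfaceome
#' screen.  Sizes are desk-scale so the whole pipeline completes in
#' seconds.
#'
#' @param seed global RNG seed; every stage derives its own stream from it.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 20230811) {
  list(
    seed = seed,
    repertoire = list(n_peptides = 400L, anchor_prob = 0.9),
    contamination = list(n_decoy = 80L, n_irt = 5L, n_blank = 10L,
                         n_modified = 20L),
    filter = list(fdr_cutoff = 0.05),
    validation = list(n_pairs = 10L, noise_cv = 0.1, n_noise_peaks = 10L,
                      rt_shift_min = 1.5, r_min = 0.9, rt_window_min = 3,
                      rt_rule_enabled = FALSE),
    annotation = list(overlap = c(HBPA = 0.1, TANTIGEN = 0.1, CTA = 0.05,
                                  IEDB = 0.1, CSPA = 0.1, DRUGGABLE = 0.05)),
    lfq = list(n_proteins = 1000L, n_per_group = 3L, frac_de = 0.05,
               log2_effect = 2, within_sd = 0.5,
               missing = list(midpoint = 21, steepness = 1)),
    de = list(fc_cutoff = 1, alpha = 0.05),
    surfaceome = list(n_lines = 7L, n_proteins = 600L, detect_prob = 0.85,
                      min_helices = 3L, k = 50L)
  )
}

ip_write_stage <- function(df, path, seed, cfg_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed: ", seed), paste0("# config: ", cfg_hash)),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full synthetic target-nomination pipeline
#'
#' Executes simulate -> filter -> motif -> restriction -> spectral
#' validation -> annotation -> differential expression -> surfaceome and
#' writes one tab-separated artifact per stage into `output_dir`, each
#' stamped with the seed and a hash of the configuration.  Deterministic:
#' the same configuration and seed produce byte-identical outputs.
#'
#' @param config configuration list (see [demo_config()]) or the path of a
#'   YAML file holding one.  Any `paths` entries are checked for existence
#'   before the first stage runs.
#' @param output_dir artifact directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return invisible list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = demo_config(), output_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) ip_stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(config$paths)) {
    missing <- unlist(config$paths)[!file.exists(unlist(config$paths))]
    if (length(missing) > 0L) {
      ip_stop("configured input path(s) do not exist: ",
              paste(missing, collapse = ", "))
    }
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  base_seed <- config$seed
  cfg_hash <- ip_fnv1a(yaml::as.yaml(config))
  emit <- function(df, name) {
    ip_write_stage(df, file.path(output_dir, name), base_seed, cfg_hash)
  }
  out <- list(config = config, config_hash = cfg_hash)

  # -- simulate the immunopeptidome ---------------------------------------
  model <- motif_a2_like(config$repertoire$anchor_prob)
  peptides <- sample_peptides(model, config$repertoire$n_peptides,
                              seed = base_seed + 1)
  ds <- make_psm_dataset(
    peptides,
    n_decoy = config$contamination$n_decoy,
    n_irt = config$contamination$n_irt,
    n_blank = config$contamination$n_blank,
    n_modified = config$contamination$n_modified,
    seed = base_seed + 2)
  emit(ds$psms, "psms.tsv")
  out$dataset <- ds

  # -- filter ladder ------------------------------------------------------
  fc <- filter_config(fdr_cutoff = config$filter$fdr_cutoff,
                      blank_peptides = ds$blank_peptides)
  report <- apply_filter_ladder(ds$psms, fc)
  emit(data.frame(step = names(report$counts),
                  count = unname(report$counts)), "filter_summary.tsv")
  emit(report$retained, "retained_peptides.tsv")
  out$filter_report <- report

  # -- length distribution and motif --------------------------------------
  retained_seqs <- report$retained$sequence
  emit(length_distribution(retained_seqs), "length_distribution.tsv")
  nonamers <- retained_seqs[nchar(retained_seqs) == 9L]
  pfm <- build_pfm(nonamers)
  uniform <- matrix(1 / 20, 20L, 9L, dimnames = dimnames(pfm))
  md <- icelogo_diff(pfm, uniform, length(nonamers))
  emit(data.frame(position = rep(colnames(pfm), each = 20L),
                  residue = rep(rownames(pfm), 9L),
                  diff_pct = as.vector(md$diff_pct),
                  p_adj = as.vector(md$p_adj),
                  enriched = as.vector(md$enriched)), "motif_diff.tsv")
  out$motif <- md

  # -- restriction via the rank surrogate ---------------------------------
  ranks <- pssm_percent_rank(nonamers, pfm, seed = base_seed + 3)
  restriction <- data.frame(peptide = nonamers,
                            allele = model$allele,
                            percent_rank = ranks,
                            category = categorize_rank(ranks),
                            stringsAsFactors = FALSE)
  emit(restriction, "restriction.tsv")
  out$restriction <- restriction

  # -- spectral validation -------------------------------------------------
  v <- config$validation
  n_pairs <- min(v$n_pairs, length(nonamers))
  val <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    pair <- simulate_spectrum_pair(nonamers[i], noise_cv = v$noise_cv,
                                   rt_shift_min = v$rt_shift_min,
                                   n_noise_peaks = v$n_noise_peaks,
                                   seed = base_seed + 100 + i)
    validate_pair(pair$endogenous, pair$synthetic, nonamers[i],
                  r_min = v$r_min, rt_window_min = v$rt_window_min,
                  rt_rule_enabled = v$rt_rule_enabled)
  }))
  emit(val, "validation.tsv")
  out$validation <- val

  # -- annotation ----------------------------------------------------------
  prot_universe <- unique(unlist(strsplit(report$retained$proteins, ";")))
  fx <- make_annotation_fixtures(retained_seqs, prot_universe,
                                 overlap = config$annotation$overlap,
                                 seed = base_seed + 4)
  annotated <- annotate(report$retained, fx$databases)
  emit(annotated, "annotated_peptides.tsv")
  sample_sets <- lapply(split(ds$psms$sequence[!ds$psms$is_decoy],
                              ds$psms$sample[!ds$psms$is_decoy]), unique)
  emit(set_intersections(sample_sets), "upset_counts.tsv")
  out$annotated <- annotated

  # -- differential expression ---------------------------------------------
  l <- config$lfq
  sim <- simulate_lfq_experiment(
    n_proteins = l$n_proteins, n_per_group = l$n_per_group,
    frac_de = l$frac_de, log2_effect = l$log2_effect,
    within_sd = l$within_sd, missing_model = l$missing,
    seed = base_seed + 5)
  pre <- preprocess_lfq(sim$lfq)
  imp <- impute_lfq(pre, seed = base_seed + 6)
  de <- differential_test(imp, fc_cutoff = config$de$fc_cutoff,
                          alpha = config$de$alpha)
  emit(de, "de_results.tsv")
  emit(volcano_table(de), "volcano.tsv")
  out$de <- de
  out$de_truth <- sim$truth

  # -- surfaceome -----------------------------------------------------------
  s <- config$surfaceome
  surf <- ip_with_seed(base_seed + 7, {
    prots <- sprintf("SP%04d", seq_len(s$n_proteins))
    line_sets <- lapply(seq_len(s$n_lines), function(i) {
      prots[stats::runif(s$n_proteins) < s$detect_prob]
    })
    names(line_sets) <- paste0("line", seq_len(s$n_lines))
    values <- matrix(stats::rlnorm(s$n_proteins * s$n_lines, 18, 1.5),
                     s$n_proteins, s$n_lines,
                     dimnames = list(prots, names(line_sets)))
    list(line_sets = line_sets,
         lfq = lfq_matrix(values,
                          stats::setNames(rep("surface", s$n_lines),
                                          names(line_sets))))
  })
  core <- shared_core(surf$line_sets)
  tm <- simulate_tm_predictions(sprintf("SP%04d", seq_len(s$n_proteins)),
                                seed = base_seed + 8)
  membrane <- tm_filter(core, tm, min_helices = s$min_helices)
  ranked <- rank_surface(membrane, surf$lfq,
                         k = min(s$k, length(membrane)))
  emit(ranked, "surfaceome.tsv")
  out$surfaceome <- ranked

  invisible(out)
}

#' Decision table for the bundled validation-candidate measurements
#'
#' The package ships measured validation results for 12 candidate
#' tumor-antigen peptides (mirror Pearson R against the synthetic standard
#' and the two retention times).  This applies the [validate_pair()]
#' decision rule to those recorded values and summarises the outcome.
#'
#' @param path tab-separated file with columns `protein`, `peptide`,
#'   `pearson_r`, `rt_experimental_min`, `rt_synthetic_min`; defaults to
#'   the packaged candidate table.
#' @inheritParams validate_pair
#' @return list: `table` (input plus `rt_diff_min` and logical `decision`),
#'   `n_pass`, `min_passing_r`, `max_passing_r`.
#' @export
table2_report <- function(path = NULL, r_min = 0.9, rt_window_min = 3.0,
                          rt_rule_enabled = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "validation_candidates.tsv",
                        package = "immunopept", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tab$rt_diff_min <- abs(tab$rt_experimental_min - tab$rt_synthetic_min)
  tab$decision <- tab$pearson_r >= r_min &
    (!rt_rule_enabled | tab$rt_diff_min <= rt_window_min)
  passing <- tab$pearson_r[tab$decision]
  list(table = tab,
       n_pass = sum(tab$decision),
       min_passing_r = if (length(passing) > 0L) min(passing) else NA_real_,
       max_passing_r = if (length(passing) > 0L) max(passing) else NA_real_)
}
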