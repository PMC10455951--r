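# Ground-truth generators.  Every generator is a pure function of its
# parameters and `seed`: the global RNG stream is saved and restored, so the
# same call always yields the same data and never perturbs the caller.
#
# The defaults encode the study conditions the downstream analysis assumes:
# HLA class I repertoires with ~65% nonamers and anchor-dominated motifs,
# PSM tables contaminated with decoys / spiked retention-time calibrants /
# blank-run carryover / modified duplicates, paired endogenous-vs-synthetic
# fragment spectra, and two-group LFQ matrices with intensity-dependent
# (missing-not-at-random) dropout.

# Fixed list of 11 synthetic retention-time calibration peptides.  These
# stand in for commercial iRT calibrant mixes: they only need to be
# recognizable contaminant sequences, not real calibrants.
IP_IRT_PEPTIDES <- c(
  "LGGNETQVR", "AGGSSEPVTGLDAK", "VEATFGVDESNAK", "YILAGVENSK",
  "TPVISGGPYEYR", "TPVITGAPYEYR", "DGLDAASYYAPVR", "ADVTPADFSEWSK",
  "GTFIIDPGGVIR", "GTFIIDPAAVIR", "LFLQFGAQGSPFLK"
)

#' Build an anchor-structured position frequency model for one HLA allotype
#'
#' Anchor positions receive their stated probability mass split equally among
#' the listed residues, with the remainder spread uniformly over the other
#' amino acids; non-anchor positions are uniform over all 20 residues.
#'
#' @param allele allotype label (e.g. `"A*02:01"`).
#' @param length peptide length the model is parameterised at (default 9).
#' @param anchors named list: names are 1-based positions, each element a
#'   list with `residues` (character vector) and `prob` (total anchor mass in
#'   (0, 1\]).
#' @return object of class `motif_model`: `allele`, `length`,
#'   `position_freqs` (20 x length column-stochastic matrix, rows named by
#'   amino acid) and `anchor_positions`.
#' @export
make_motif_model <- function(allele, length = 9L, anchors = list()) {
  freqs <- matrix(1 / 20, nrow = 20L, ncol = length,
                  dimnames = list(IP_AA, paste0("P", seq_len(length))))
  anchor_pos <- integer(0)
  for (pos_chr in names(anchors)) {
    pos <- as.integer(pos_chr)
    spec <- anchors[[pos_chr]]
    if (pos < 1L || pos > length) {
      ip_stop("anchor position ", pos, " outside 1..", length)
    }
    if (!is.numeric(spec$prob) || spec$prob <= 0 || spec$prob > 1) {
      ip_stop("anchor probability must be in (0, 1]")
    }
    res <- match.arg(spec$residues, IP_AA, several.ok = TRUE)
    col <- rep((1 - spec$prob) / (20 - length(res)), 20L)
    names(col) <- IP_AA
    if (spec$prob == 1) col[] <- 0
    col[res] <- spec$prob / length(res)
    freqs[, pos] <- col
    anchor_pos <- c(anchor_pos, pos)
  }
  stopifnot(all(abs(colSums(freqs) - 1) < 1e-9))
  structure(list(allele = allele, length = as.integer(length),
                 position_freqs = freqs,
                 anchor_positions = sort(anchor_pos)),
            class = "motif_model")
}

#' Bundled allotype-like motif specifications
#'
#' `motif_a2_like()` places Leu/Met at P2 and Leu/Val at the C-terminus
#' (the canonical A*02:01 anchor pattern); `motif_a3_like()` places Lys/Arg
#' at P1 and the C-terminus.  The A3-like model's P1 anchor follows the
#' position convention used by the immunopeptidome repertoires this
#' generator emulates; pass explicit `anchors` to [make_motif_model()] for
#' the textbook P2/P9 variant.
#'
#' @param anchor_prob total probability mass per anchor position.
#' @export
motif_a2_like <- function(anchor_prob = 0.9) {
  make_motif_model("A*02:01", 9L, list(
    "2" = list(residues = c("L", "M"), prob = anchor_prob),
    "9" = list(residues = c("L", "V"), prob = anchor_prob)))
}

#' @rdname motif_a2_like
#' @export
motif_a3_like <- function(anchor_prob = 0.9) {
  make_motif_model("A*03:01", 9L, list(
    "1" = list(residues = c("K", "R"), prob = anchor_prob),
    "9" = list(residues = c("K", "R"), prob = anchor_prob)))
}

# Default class I length distribution: ~65% nonamers.
IP_LENGTH_DIST <- c("8" = 0.03, "9" = 0.65, "10" = 0.20, "11" = 0.10,
                    "12" = 0.02)

#' Sample a peptide repertoire from a motif model
#'
#' Peptides of the model's native length draw each position from the model.
#' Other lengths draw non-anchor positions uniformly, with the model's
#' anchor columns remapped: the C-terminal anchor follows the new
#' C-terminus, any other anchor keeps its absolute position.
#'
#' @param model `motif_model`.
#' @param n number of peptides (>= 1).
#' @param length_dist named probability vector over lengths 8-12 (must sum
#'   to 1); default ~65% nonamers.
#' @param seed RNG seed.
#' @return character vector of `n` peptides.
#' @export
sample_peptides <- function(model, n, length_dist = IP_LENGTH_DIST, seed) {
  if (n < 1L) ip_stop("n must be >= 1")
  if (abs(sum(length_dist) - 1) > 1e-9) {
    ip_stop("length_dist must sum to 1")
  }
  lens <- as.integer(names(length_dist))
  ip_with_seed(seed, {
    drawn <- lens[sample.int(length(lens), n, replace = TRUE,
                             prob = length_dist)]
    vapply(drawn, function(L) {
      cols <- lapply(seq_len(L), function(pos) {
        if (L == model$length) {
          model$position_freqs[, pos]
        } else {
          src <- NA_integer_
          for (a in model$anchor_positions) {
            mapped <- if (a == model$length) L else a
            if (mapped == pos && mapped <= L) src <- a
          }
          if (is.na(src)) rep(1 / 20, 20L) else model$position_freqs[, src]
        }
      })
      paste(vapply(cols, function(p) sample(IP_AA, 1L, prob = p),
                   character(1)), collapse = "")
    }, character(1))
  })
}

#' Generate a contaminated PSM table with known truth labels
#'
#' True PSMs draw scores from the `score_true` normal; contaminants are (i)
#' decoys — composition-preserving shuffles of true sequences flagged with
#' the `DECOY_` accession prefix and drawn from the stochastically smaller
#' `score_decoy` normal, (ii) spiked retention-time calibrant peptides,
#' (iii) blank-carryover peptides that appear both in a sample and in the
#' returned blank-run set, and (iv) modified duplicates — a true PSM
#' replicated with one modification added.
#'
#' @param true_peptides character vector of genuine peptide sequences.
#' @param n_decoy,n_irt,n_blank,n_modified contamination counts; `n_decoy`
#'   and `n_modified` may not exceed the number of true peptides, `n_irt`
#'   may not exceed 11 (the calibrant list length).
#' @param score_true,score_decoy `c(mean, sd)` of the score distributions.
#' @param samples sample labels cycled over true PSMs.
#' @param seed RNG seed.
#' @return list: `psms` (canonical PSM data frame), `blank_peptides`
#'   (character set), `truth` (data frame `row`, `sequence`, `label` with
#'   label one of true/decoy/irt/blank/modified).
#' @export
make_psm_dataset <- function(true_peptides, n_decoy = 0L, n_irt = 0L,
                             n_blank = 0L, n_modified = 0L,
                             score_true = c(30, 5), score_decoy = c(18, 5),
                             samples = c("S1", "S2"), seed) {
  n_true <- length(true_peptides)
  if (n_decoy > n_true || n_modified > n_true) {
    ip_stop("contamination counts exceed the number of true peptides")
  }
  if (n_irt > length(IP_IRT_PEPTIDES)) {
    ip_stop("at most ", length(IP_IRT_PEPTIDES), " calibrant peptides available")
  }
  ip_with_seed(seed, {
    row_of <- function(seqs, score_mu, score_sd, is_decoy, proteins, mods = "") {
      k <- length(seqs)
      if (k == 0L) return(NULL)
      data.frame(
        sequence = seqs,
        modifications = rep_len(mods, k),
        score = stats::rnorm(k, score_mu, score_sd),
        q_value = NA_real_,
        is_decoy = is_decoy,
        sample = sample(samples, k, replace = TRUE),
        antibody = "pan-classI",
        rt_min = stats::runif(k, 10, 120),
        intensity = stats::rlnorm(k, 18, 1),
        proteins = proteins,
        stringsAsFactors = FALSE
      )
    }
    # assign source proteins so that some proteins carry several peptides
    n_prot <- max(1L, ceiling(n_true / 2))
    prot_pool <- sprintf("PR%04d", seq_len(n_prot))
    true_prot <- sample(prot_pool, n_true, replace = TRUE)
    true_rows <- row_of(true_peptides, score_true[1], score_true[2],
                        FALSE, true_prot)
    shuffle <- function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }
    decoy_seq <- vapply(sample(true_peptides, n_decoy), shuffle, character(1))
    decoy_rows <- row_of(decoy_seq, score_decoy[1], score_decoy[2], TRUE,
                         paste0("DECOY_", sample(prot_pool, n_decoy,
                                                 replace = TRUE)))
    irt_seq <- IP_IRT_PEPTIDES[seq_len(n_irt)]
    irt_rows <- row_of(irt_seq, score_true[1], score_true[2], FALSE, "IRT_STD")
    blank_seq <- ip_random_peptides(n_blank, 9L)
    blank_rows <- row_of(blank_seq, score_true[1], score_true[2], FALSE,
                         sample(prot_pool, max(n_blank, 1L),
                                replace = TRUE)[seq_len(n_blank)])
    mod_idx <- if (n_modified > 0L) sample(n_true, n_modified) else integer(0)
    mod_rows <- NULL
    if (n_modified > 0L) {
      mod_rows <- true_rows[mod_idx, , drop = FALSE]
      mod_rows$modifications <- "1|Oxidation"
      mod_rows$score <- stats::rnorm(n_modified, score_true[1], score_true[2])
    }
    psms <- rbind(true_rows, decoy_rows, irt_rows, blank_rows, mod_rows)
    truth <- data.frame(
      row = seq_len(nrow(psms)),
      sequence = psms$sequence,
      label = rep(c("true", "decoy", "irt", "blank", "modified"),
                  times = c(n_true, n_decoy, n_irt, n_blank, n_modified)),
      stringsAsFactors = FALSE
    )
    perm <- sample(nrow(psms))
    psms <- psms[perm, , drop = FALSE]
    truth <- truth[perm, , drop = FALSE]
    truth$row <- seq_len(nrow(truth))
    rownames(psms) <- rownames(truth) <- NULL
    list(psms = psms, blank_peptides = unique(blank_seq), truth = truth)
  })
}

#' Simulate a paired endogenous / synthetic-standard spectrum
#'
#' Both spectra contain every singly-charged b/y ion of the peptide.  Base
#' fragment intensities are drawn log-normal (sdlog = 1) once per pair, then
#' perturbed independently in each spectrum by multiplicative log-normal
#' noise of the stated coefficient of variation, so the mirror correlation
#' degrades smoothly with `noise_cv` and equals 1 exactly at `noise_cv = 0`.
#' Uniform random noise peaks (kept clear of the fragment windows) are
#' appended, and the synthetic standard elutes `rt_shift_min` later.
#'
#' @param peptide sequence of length 8-12.
#' @param noise_cv relative intensity noise (CV) applied per spectrum.
#' @param rt_shift_min retention-time offset of the synthetic run (minutes).
#' @param n_noise_peaks number of random non-fragment peaks per spectrum.
#' @param seed RNG seed.
#' @return list with `spectrum` objects `endogenous` and `synthetic`.
#' @export
simulate_spectrum_pair <- function(peptide, noise_cv = 0.1,
                                   rt_shift_min = 1.0, n_noise_peaks = 10L,
                                   seed) {
  L <- nchar(peptide)
  if (L < 8L || L > 12L) ip_stop("peptide length must be 8-12")
  frags <- theoretical_fragments(peptide)
  ip_with_seed(seed, {
    base <- stats::rlnorm(nrow(frags), meanlog = 10, sdlog = 1)
    perturb <- function(x) {
      if (noise_cv == 0) return(x)
      sdlog <- sqrt(log(1 + noise_cv^2))
      x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    noise_peaks <- function() {
      if (n_noise_peaks == 0L) {
        return(matrix(numeric(0), ncol = 2L))
      }
      lo <- 100
      hi <- max(frags$mz) + 100
      mz <- numeric(0)
      while (length(mz) < n_noise_peaks) {
        cand <- stats::runif(n_noise_peaks, lo, hi)
        cand <- cand[vapply(cand, function(m) {
          all(abs(frags$mz - m) > 0.05)
        }, logical(1))]
        mz <- c(mz, cand)
      }
      mz <- mz[seq_len(n_noise_peaks)]
      cbind(mz, stats::runif(n_noise_peaks, 0, stats::median(base) / 5))
    }
    rt <- stats::runif(1, 10, 120)
    mk <- function(title, ints, rt_min) {
      spectrum(title, precursor_mz(peptide), 1L, rt_min,
               rbind(cbind(frags$mz, ints), noise_peaks()))
    }
    list(endogenous = mk(paste0(peptide, "_endogenous"), perturb(base), rt),
         synthetic = mk(paste0(peptide, "_synthetic"), perturb(base),
                        rt + rt_shift_min))
  })
}

#' Simulate a two-group LFQ experiment with MNAR dropout
#'
#' Protein baseline log2 abundances are normal; a fraction `frac_de` of
#' proteins is shifted by `log2_effect` (random sign) in the first group.
#' Dropout is missing-not-at-random: an observation at log2 intensity x is
#' lost with probability `1 / (1 + exp(steepness * (x - midpoint)))`, i.e.
#' dropout decreases with intensity.  Returned intensities are on the raw
#' (linear) scale so the full preprocess -> impute -> test workflow applies.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group samples per group.
#' @param frac_de fraction of proteins differentially expressed in \[0, 1\].
#' @param log2_effect absolute planted log2 fold change.
#' @param within_sd within-group log2 SD.
#' @param missing_model list with `midpoint` (log2 intensity of 50% dropout)
#'   and `steepness`; set `midpoint = -Inf` for a complete matrix.
#' @param groups two group labels (first group carries the effect).
#' @param base_mean,base_sd distribution of protein baseline log2 means.
#' @param seed RNG seed.
#' @return list: `lfq` (`lfq_matrix`, raw scale) and `truth` (data frame
#'   `protein`, `is_de`, `log2_effect` signed effect in group 1).
#' @export
simulate_lfq_experiment <- function(n_proteins = 2000L, n_per_group = 3L,
                                    frac_de = 0.05, log2_effect = 2,
                                    within_sd = 0.5,
                                    missing_model = list(midpoint = 21,
                                                         steepness = 1),
                                    groups = c("DIPG", "PB"),
                                    base_mean = 25, base_sd = 2, seed) {
  if (frac_de < 0 || frac_de > 1) ip_stop("frac_de must be in [0, 1]")
  n_de <- round(frac_de * n_proteins)
  ip_with_seed(seed, {
    prots <- sprintf("PR%05d", seq_len(n_proteins))
    de_idx <- if (n_de > 0L) sample(n_proteins, n_de) else integer(0)
    effect <- numeric(n_proteins)
    effect[de_idx] <- log2_effect * sample(c(-1, 1), n_de, replace = TRUE)
    mu <- stats::rnorm(n_proteins, base_mean, base_sd)
    samples <- c(paste0(groups[1], "_", seq_len(n_per_group)),
                 paste0(groups[2], "_", seq_len(n_per_group)))
    grp <- stats::setNames(rep(groups, each = n_per_group), samples)
    means <- cbind(matrix(mu + effect, n_proteins, n_per_group),
                   matrix(mu, n_proteins, n_per_group))
    x <- means + stats::rnorm(length(means), 0, within_sd)
    p_drop <- 1 / (1 + exp(missing_model$steepness *
                             (x - missing_model$midpoint)))
    x[stats::runif(length(x)) < p_drop] <- NA
    dimnames(x) <- list(prots, samples)
    list(lfq = lfq_matrix(2^x, grp, log2 = FALSE),
         truth = data.frame(protein = prots,
                            is_de = seq_len(n_proteins) %in% de_idx,
                            log2_effect = effect,
                            stringsAsFactors = FALSE))
  })
}

#' Build annotation databases with known overlap against a universe
#'
#' Each database receives the stated fraction of the corresponding universe
#' (peptide universe for peptide-level databases, protein universe for
#' protein-level ones) plus `n_distractors` members absent from the
#' universe.
#'
#' @param peptides peptide universe (sequences).
#' @param proteins protein universe (accessions).
#' @param overlap named numeric vector of overlap fractions in \[0, 1\];
#'   names among HBPA, TANTIGEN, CTA, IEDB, CSPA, DRUGGABLE.  TANTIGEN, CTA
#'   and IEDB are peptide-level; HBPA, CSPA and DRUGGABLE protein-level.
#' @param n_distractors non-universe members per database.
#' @param seed RNG seed.
#' @return list: `databases` (list of `annotation_db`) and `truth` (list of
#'   in-universe member vectors per database).
#' @export
make_annotation_fixtures <- function(peptides, proteins,
                                     overlap = c(HBPA = 0.1, TANTIGEN = 0.1,
                                                 CTA = 0.1, IEDB = 0.1,
                                                 CSPA = 0.1, DRUGGABLE = 0.1),
                                     n_distractors = 20L, seed) {
  if (any(overlap < 0 | overlap > 1)) {
    ip_stop("overlap fractions must be in [0, 1]")
  }
  kinds <- c(HBPA = "protein", TANTIGEN = "peptide", CTA = "peptide",
             IEDB = "peptide", CSPA = "protein", DRUGGABLE = "protein")
  ip_with_seed(seed, {
    dbs <- list()
    truth <- list()
    for (nm in names(overlap)) {
      kind <- kinds[[nm]]
      if (is.null(kind)) kind <- "peptide"
      universe <- if (kind == "peptide") unique(peptides) else unique(proteins)
      n_in <- round(overlap[[nm]] * length(universe))
      members_in <- if (n_in > 0L) sample(universe, n_in) else character(0)
      distract <- if (kind == "peptide") {
        ip_random_peptides(n_distractors, 9L)
      } else {
        sprintf("XX%s%04d", substr(nm, 1, 2),
                sample(10^4 - 1, n_distractors))
      }
      distract <- setdiff(distract, universe)
      truth[[nm]] <- members_in
      dbs[[nm]] <- annotation_db(nm, kind, c(members_in, distract))
    }
    list(databases = dbs, truth = truth)
  })
}

#' Simulate transmembrane helix predictions for a protein set
#'
#' A stand-in for an external topology predictor: a fraction of proteins is
#' membrane-like with a Poisson(+1) helix count, the rest have zero helices.
#'
#' @param proteins accession vector.
#' @param frac_membrane fraction with >= 1 predicted helix.
#' @param mean_helices Poisson mean of additional helices beyond the first.
#' @param seed RNG seed.
#' @return data frame `protein`, `pred_hel`.
#' @export
simulate_tm_predictions <- function(proteins, frac_membrane = 0.4,
                                    mean_helices = 4, seed) {
  ip_with_seed(seed, {
    is_mem <- stats::runif(length(proteins)) < frac_membrane
    hel <- integer(length(proteins))
    hel[is_mem] <- 1L + stats::rpois(sum(is_mem), mean_helices)
    data.frame(protein = proteins, pred_hel = hel, stringsAsFactors = FALSE)
  })
}
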