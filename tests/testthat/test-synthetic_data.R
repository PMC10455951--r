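test_that("motif models place anchor mass as specified", {
  m <- motif_a2_like(0.9)
  expect_equal(unname(m$position_freqs["L", 2]), 0.45)
  expect_equal(unname(m$position_freqs["M", 2]), 0.45)
  expect_equal(unname(m$position_freqs["L", 9]), 0.45)
  expect_equal(colSums(m$position_freqs), rep(1, 9), tolerance = 1e-9,
               ignore_attr = TRUE)
  # degenerate single-residue anchor with full mass is deterministic
  d <- make_motif_model("X", 9L, list("2" = list(residues = "L", prob = 1)))
  expect_equal(unname(d$position_freqs["L", 2]), 1)
  expect_equal(sum(d$position_freqs[, 2] > 0), 1L)
  # A3-like model anchors at P1 and P9
  a3 <- motif_a3_like()
  expect_equal(a3$anchor_positions, c(1L, 9L))
  expect_equal(unname(a3$position_freqs["K", 1]), 0.45)
  expect_error(make_motif_model("X", 9L,
                                list("2" = list(residues = "L", prob = 1.2))))
})

test_that("sampled repertoires reproduce anchor frequencies and length mix", {
  m <- motif_a2_like()
  peps <- sample_peptides(m, 2000L,
                          length_dist = c("9" = 1), seed = 42)
  expect_true(all(nchar(peps) == 9L))
  p2 <- substr(peps, 2, 2)
  expect_lt(abs(mean(p2 %in% c("L", "M")) - 0.9), 0.03)
  # determinism
  expect_identical(peps, sample_peptides(m, 2000L, c("9" = 1), seed = 42))
  # default length distribution: nonamer fraction near 0.65 at n = 5000
  peps5 <- sample_peptides(m, 5000L, seed = 7)
  frac9 <- mean(nchar(peps5) == 9L)
  expect_gte(frac9, 0.63)
  expect_lte(frac9, 0.67)
  # non-nonamers keep the C-terminal anchor at their own C-terminus
  p10 <- peps5[nchar(peps5) == 10L]
  expect_gt(mean(substr(p10, 10, 10) %in% c("L", "V")), 0.8)
})

test_that("contaminated PSM datasets partition into labelled truth classes", {
  peps <- sample_peptides(motif_a2_like(), 100L, c("9" = 1), seed = 1)
  peps <- unique(peps)
  ds <- make_psm_dataset(peps, n_decoy = 20L, n_irt = 5L, n_blank = 5L,
                         n_modified = 10L, seed = 9)
  expect_equal(nrow(ds$psms), length(peps) + 40L)
  expect_equal(nrow(ds$truth), nrow(ds$psms))
  tab <- table(ds$truth$label)
  expect_equal(unname(tab[c("true", "decoy", "irt", "blank", "modified")]),
               c(length(peps), 20L, 5L, 5L, 10L), ignore_attr = TRUE)
  expect_true(all(ds$psms$is_decoy[ds$truth$label == "decoy"]))
  expect_true(all(ds$psms$sequence[ds$truth$label == "blank"] %in%
                    ds$blank_peptides))
  expect_true(all(nzchar(ds$psms$modifications[ds$truth$label == "modified"])))
  # zero contamination -> table is exactly the true PSMs
  clean <- make_psm_dataset(peps, seed = 9)
  expect_setequal(clean$psms$sequence, peps)
  expect_true(all(clean$truth$label == "true"))
  # determinism: identical tables under the same seed
  ds2 <- make_psm_dataset(peps, n_decoy = 20L, n_irt = 5L, n_blank = 5L,
                          n_modified = 10L, seed = 9)
  expect_identical(ds$psms, ds2$psms)
  expect_error(make_psm_dataset(peps, n_decoy = length(peps) + 1L, seed = 1))
})

test_that("generated scores are stochastically ordered (true above decoy)", {
  peps <- unique(sample_peptides(motif_a2_like(), 300L, c("9" = 1), seed = 3))
  ds <- make_psm_dataset(peps, n_decoy = 100L, seed = 4)
  w <- wilcox.test(ds$psms$score[!ds$psms$is_decoy],
                   ds$psms$score[ds$psms$is_decoy],
                   alternative = "greater")
  expect_lt(w$p.value, 1e-10)
})

test_that("spectrum pairs contain the full b/y ladder and honour noise and RT settings", {
  pair <- simulate_spectrum_pair("IVDPGYLGY", noise_cv = 0,
                                 n_noise_peaks = 0L, rt_shift_min = 1.9,
                                 seed = 5)
  frags <- theoretical_fragments("IVDPGYLGY")
  expect_equal(nrow(frags), 16L)
  for (sp in pair) {
    hits <- vapply(frags$mz, function(mz) {
      any(abs(sp$peaks[, "mz"] - mz) < 1e-9)
    }, logical(1))
    expect_true(all(hits))
  }
  # noiseless: identical intensities
  expect_equal(pair$endogenous$peaks, pair$synthetic$peaks)
  expect_equal(pair$synthetic$rt_min - pair$endogenous$rt_min, 1.9)
  expect_error(simulate_spectrum_pair("PEPTIDE", seed = 1), "8-12")
})

test_that("LFQ simulation plants the stated effects and dropout behaviour", {
  sim <- simulate_lfq_experiment(n_proteins = 2000L, frac_de = 0.05,
                                 seed = 11)
  expect_equal(sum(sim$truth$is_de), 100L)
  expect_equal(dim(sim$lfq$values), c(2000L, 6L))
  expect_false(sim$lfq$log2)
  expect_true(anyNA(sim$lfq$values))
  # midpoint far below all intensities -> complete matrix
  full <- simulate_lfq_experiment(n_proteins = 200L,
                                  missing_model = list(midpoint = -1e6,
                                                       steepness = 1),
                                  seed = 11)
  expect_false(anyNA(full$lfq$values))
  # null case: group mean differences centred at zero
  null <- simulate_lfq_experiment(n_proteins = 500L, frac_de = 0,
                                  missing_model = list(midpoint = -1e6,
                                                       steepness = 1),
                                  seed = 12)
  x <- log2(null$lfq$values)
  diffs <- rowMeans(x[, 1:3]) - rowMeans(x[, 4:6])
  expect_lt(abs(mean(diffs)), 0.05)
  # dropout hits low-abundance proteins preferentially
  n_miss <- rowSums(is.na(sim$lfq$values))
  obs_mean <- rowMeans(log2(sim$lfq$values), na.rm = TRUE)
  ok <- is.finite(obs_mean)
  expect_lt(cor(obs_mean[ok], n_miss[ok]), -0.3)
})

test_that("annotation fixtures contain the stated universe overlap plus distractors", {
  peps <- unique(sample_peptides(motif_a2_like(), 120L, c("9" = 1), seed = 2))
  prots <- sprintf("PR%03d", 1:50)
  fx <- make_annotation_fixtures(peps[1:100], prots,
                                 overlap = c(IEDB = 0.1, CSPA = 0.2),
                                 seed = 6)
  expect_equal(length(fx$truth$IEDB), 10L)
  expect_equal(length(fx$truth$CSPA), 10L)
  expect_true(all(fx$truth$IEDB %in% peps[1:100]))
  expect_true(all(fx$truth$CSPA %in% prots))
  expect_equal(fx$databases$IEDB$kind, "peptide")
  expect_equal(fx$databases$CSPA$kind, "protein")
  # distractors are outside the universe
  expect_true(length(setdiff(fx$databases$IEDB$members, peps[1:100])) > 0)
  fx2 <- make_annotation_fixtures(peps[1:100], prots,
                                  overlap = c(IEDB = 0.1, CSPA = 0.2),
                                  seed = 6)
  expect_identical(fx$databases, fx2$databases)
})

test_that("generators never perturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(sample_peptides(motif_a2_like(), 10L, c("9" = 1), seed = 1))
  invisible(simulate_lfq_experiment(n_proteins = 10L, seed = 2))
  expect_identical(.Random.seed, before)
})
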