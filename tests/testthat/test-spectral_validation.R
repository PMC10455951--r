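test_that("b/y fragment masses agree with an elemental-composition oracle", {
  frag <- theoretical_fragments("PEPTIDE")
  oracle <- oracle_fragment_mz("PEPTIDE")
  b <- frag$mz[frag$series == "b"]
  y <- frag$mz[frag$series == "y"]
  expect_equal(b, oracle$b, tolerance = 1e-3 / max(oracle$b))
  expect_equal(y, oracle$y, tolerance = 1e-3 / max(oracle$y))
  expect_equal(b[2], 227.1026, tolerance = 1e-3 / 227)
  expect_equal(max(frag$index), 6L)
  expect_equal(peptide_mass("PEPTIDE"), 799.3600, tolerance = 1e-3 / 799)
  # 50 random peptides against the oracle, all fragments within 0.001 Th
  set.seed(41)
  for (i in 1:50) {
    pep <- paste(sample(names(immunopept:::IP_MONO_MASS), sample(8:12, 1),
                        replace = TRUE), collapse = "")
    fr <- theoretical_fragments(pep)
    or <- oracle_fragment_mz(pep)
    expect_true(all(abs(fr$mz[fr$series == "b"] - or$b) < 1e-3))
    expect_true(all(abs(fr$mz[fr$series == "y"] - or$y) < 1e-3))
    expect_equal(nrow(fr), 2L * (nchar(pep) - 1L))
  }
  expect_error(theoretical_fragments("PEPTIDEZ"),
               class = "immunopept_format_error")
})

test_that("doubly-charged fragments halve the protonated mass", {
  fr <- theoretical_fragments("IVDPGYLGY", max_charge = 2L)
  one <- fr[fr$charge == 1L, ]
  two <- fr[fr$charge == 2L, ]
  expect_equal(two$mz, (one$mz + immunopept:::IP_PROTON) / 2)
})

test_that("intensity projection uses the tolerance window and nearest-peak rule", {
  frags <- theoretical_fragments("IVDPGYLGY")
  target <- frags$mz[1]
  # a peak 0.05 Th away contributes nothing at 0.02 tolerance
  far <- spectrum("far", 500, 1L, 10, cbind(target + 0.05, 100))
  near <- spectrum("near", 500, 1L, 10, cbind(target + 0.01, 50))
  v <- match_intensity_vectors(far, near, frags)
  expect_equal(v$a[1], 0)
  expect_equal(v$b[1], 50)
  # two candidate peaks in the window: nearest wins
  duo <- spectrum("duo", 500, 1L, 10,
                  cbind(c(target - 0.015, target + 0.005), c(10, 20)))
  v2 <- match_intensity_vectors(duo, duo, frags)
  expect_equal(v2$a[1], 20)
  # a noiseless simulated pair is positive at every fragment entry
  pair <- simulate_spectrum_pair("IVDPGYLGY", noise_cv = 0,
                                 n_noise_peaks = 0L, seed = 3)
  v3 <- match_intensity_vectors(pair$endogenous, pair$synthetic, frags)
  expect_true(all(v3$a > 0) && all(v3$b > 0))
  expect_length(v3$a, nrow(frags))
})

test_that("mirror Pearson matches closed form and signals zero variance distinctly", {
  expect_equal(mirror_pearson(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(mirror_pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(mirror_pearson(c(1, 2, 3, 4), c(1, 2, 3, 8)),
               11 / sqrt(145), tolerance = 1e-10)
  expect_error(mirror_pearson(c(1, 1, 1), c(1, 2, 3)),
               class = "immunopept_zero_variance")
  expect_error(mirror_pearson(c(1, 2), c(1, 2)))
})

test_that("mirror Pearson is symmetric and scale-invariant", {
  set.seed(5)
  a <- runif(16)
  b <- runif(16)
  expect_equal(mirror_pearson(a, b), mirror_pearson(b, a))
  expect_equal(mirror_pearson(3.7 * a + 2, b), mirror_pearson(a, b))
})

test_that("pair validation applies the correlation and optional RT rules", {
  pair <- simulate_spectrum_pair("IVDPGYLGY", noise_cv = 0,
                                 n_noise_peaks = 0L, rt_shift_min = 1.9,
                                 seed = 8)
  res <- validate_pair(pair$endogenous, pair$synthetic, "IVDPGYLGY")
  expect_equal(res$pearson_r, 1.0)
  expect_true(res$decision)
  expect_equal(res$n_matched_fragments, 16L)
  expect_equal(res$rt_synthetic_min - res$rt_endogenous_min, 1.9)
  # enabling the RT rule fails a pair shifted beyond the window
  far <- simulate_spectrum_pair("IVDPGYLGY", noise_cv = 0,
                                n_noise_peaks = 0L, rt_shift_min = 5,
                                seed = 8)
  strict <- validate_pair(far$endogenous, far$synthetic, "IVDPGYLGY",
                          rt_rule_enabled = TRUE)
  expect_false(strict$decision)
  lax <- validate_pair(far$endogenous, far$synthetic, "IVDPGYLGY")
  expect_true(lax$decision)
})

test_that("mirror correlation degrades monotonically with noise and separates mismatches", {
  model <- motif_a2_like()
  peps <- sample_peptides(model, 200L, c("9" = 1), seed = 51)
  med_r <- vapply(c(0, 0.1, 0.5, 1.0), function(cv) {
    rs <- vapply(seq_along(peps), function(i) {
      pair <- simulate_spectrum_pair(peps[i], noise_cv = cv,
                                     n_noise_peaks = 5L, seed = 6000 + i)
      validate_pair(pair$endogenous, pair$synthetic, peps[i])$pearson_r
    }, numeric(1))
    median(rs)
  }, numeric(1))
  expect_equal(med_r[1], 1.0)
  expect_true(all(diff(med_r) < 0))
  # mismatched peptides: spectra of two different random 9-mers
  mis <- vapply(1:200, function(i) {
    p <- immunopept:::ip_with_seed(7000 + i,
                                   immunopept:::ip_random_peptides(2, 9L))
    a <- simulate_spectrum_pair(p[1], noise_cv = 0.1, seed = 7500 + i)
    b <- simulate_spectrum_pair(p[2], noise_cv = 0.1, seed = 7700 + i)
    frags <- theoretical_fragments(p[1])
    v <- match_intensity_vectors(a$endogenous, b$synthetic, frags)
    if (sd(v$a) == 0 || sd(v$b) == 0) return(0)
    mirror_pearson(v$a, v$b)
  }, numeric(1))
  expect_lt(median(mis), 0.5)
})

test_that("mirror-plot exports carry signed intensities on the fragment basis", {
  pair <- simulate_spectrum_pair("SLLQHLIGL", noise_cv = 0,
                                 n_noise_peaks = 0L, seed = 9)
  mp <- mirror_plot_data(pair$endogenous, pair$synthetic, "SLLQHLIGL")
  expect_equal(nrow(mp), 16L)
  expect_true(all(mp$intensity_up >= 0))
  expect_true(all(mp$intensity_down <= 0))
  expect_equal(mp$intensity_up, -mp$intensity_down)
})
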