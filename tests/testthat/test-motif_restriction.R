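test_that("length distributions count and normalise correctly", {
  peps <- c(rep("AAAAAAAAA", 6), rep("AAAAAAAAAA", 4))
  ld <- length_distribution(peps)
  expect_equal(ld$fraction[ld$length == 9], 0.6)
  expect_equal(sum(ld$fraction), 1)
  all9 <- length_distribution(rep("CCCCCCCCC", 5))
  expect_equal(all9$fraction[all9$length == 9], 1)
  empty <- length_distribution(character(0))
  expect_true(all(empty$count == 0L))
  expect_true(all(is.na(empty$fraction)))
  expect_error(length_distribution("AAAAAAAAAAAAA"),
               class = "immunopept_precondition_error")
})

test_that("position frequency matrices are column-stochastic with smoothing", {
  pfm <- build_pfm(c("AAA", "AAC"))
  expect_equal(unname(pfm["A", 3]), 0.5)
  expect_equal(unname(pfm["C", 3]), 0.5)
  expect_equal(colSums(pfm), rep(1, 3), ignore_attr = TRUE)
  one <- build_pfm("ACD")
  expect_equal(unname(one["A", 1]), 1)
  expect_equal(sum(one > 0), 3L)
  sm <- build_pfm(c("AAA", "AAA"), pseudocount = 1)
  expect_equal(unname(sm["C", 1]), 1 / (2 + 20))
  expect_equal(colSums(sm), rep(1, 3), ignore_attr = TRUE)
  expect_error(build_pfm(c("AAA", "AAAA")),
               class = "immunopept_precondition_error")
})

test_that("logo-style differences score percentage points with exact binomial tests", {
  obs <- matrix(1 / 20, 20, 2, dimnames = list(immunopept:::IP_AA, NULL))
  ref <- obs
  obs["L", 1] <- 0.60
  obs[setdiff(rownames(obs), "L"), 1] <- 0.40 / 19
  ref["L", 1] <- 0.05
  ref[setdiff(rownames(ref), "L"), 1] <- 0.95 / 19
  md <- icelogo_diff(obs, ref, n_observed = 200)
  expect_equal(unname(md$diff_pct["L", 1]), 55)
  expect_true(unname(md$enriched["L", 1]))
  # Bonferroni-corrected p agrees with a direct binom.test call
  raw <- binom.test(round(0.60 * 200), 200, 0.05)$p.value
  expect_equal(unname(md$p_value["L", 1]), raw)
  expect_equal(unname(md$p_adj["L", 1]), min(1, raw * length(obs)))
  # null: observed equals reference, nothing flagged
  null <- icelogo_diff(ref, ref, n_observed = 200)
  expect_true(all(null$diff_pct == 0))
  expect_false(any(null$enriched))
  expect_error(icelogo_diff(obs, ref[, 1, drop = FALSE], 10),
               class = "immunopept_precondition_error")
})

test_that("planted anchors are recovered as the enriched-significant cells", {
  model <- motif_a2_like()
  peps <- sample_peptides(model, 2000L, c("9" = 1), seed = 77)
  pfm <- build_pfm(peps)
  uniform <- matrix(1 / 20, 20, 9, dimnames = dimnames(pfm))
  md <- icelogo_diff(pfm, uniform, length(peps))
  flagged <- which(md$enriched, arr.ind = TRUE)
  planted <- rbind(c(which(rownames(pfm) == "L"), 2),
                   c(which(rownames(pfm) == "M"), 2),
                   c(which(rownames(pfm) == "L"), 9),
                   c(which(rownames(pfm) == "V"), 9))
  expect_setequal(paste(flagged[, 1], flagged[, 2]),
                  paste(planted[, 1], planted[, 2]))
})

test_that("rank categories partition the non-negative line with SB/WB boundaries", {
  expect_equal(as.character(categorize_rank(0.3)), "SB")
  expect_equal(as.character(categorize_rank(0.5)), "SB")
  expect_equal(as.character(categorize_rank(2.0)), "WB")
  expect_equal(as.character(categorize_rank(2.01)), "NB")
  grid <- c(0, 10^seq(-3, 1, length.out = 200), 0.5, 2.0, 0.5 + 1e-12,
            2 + 1e-12, 100)
  cats <- categorize_rank(grid)
  manual <- ifelse(grid <= 0.5, "SB", ifelse(grid <= 2, "WB", "NB"))
  expect_equal(as.character(cats), manual)
  expect_equal(sum(is.na(cats)), 0L)
  expect_error(categorize_rank(-0.1),
               class = "immunopept_precondition_error")
})

test_that("restriction assignment takes the best rank with deterministic tie-breaks", {
  r <- assign_restriction(c("A*02:01" = 0.1, "B*44:02" = 1.5))
  expect_equal(r$allele, "A*02:01")
  expect_equal(r$category, "SB")
  # all non-binders -> unassigned
  un <- assign_restriction(c("A*02:01" = 3, "B*44:02" = 2.5))
  expect_equal(un$category, "unassigned")
  expect_true(is.na(un$allele))
  # tie broken lexicographically
  tie <- assign_restriction(c("C*04:01" = 0.4, "A*01:01" = 0.4))
  expect_equal(tie$allele, "A*01:01")
  # invariant to input ordering
  fwd <- assign_restriction(c("A*01:01" = 0.7, "B*08:01" = 0.6))
  rev <- assign_restriction(c("B*08:01" = 0.6, "A*01:01" = 0.7))
  expect_identical(fwd, rev)
  # SB-only mode leaves weak binders unassigned
  wb <- assign_restriction(c("A*02:01" = 1.0), sb_only = TRUE)
  expect_equal(wb$category, "unassigned")
  expect_error(assign_restriction(numeric(0)),
               class = "immunopept_precondition_error")
})

test_that("restriction tables preserve peptide order and per-peptide results", {
  ranks <- data.frame(
    peptide = c("SLLQHLIGL", "SLLQHLIGL", "IVDPGYLGY"),
    allele = c("A*02:01", "B*44:02", "A*01:01"),
    percent_rank = c(0.2, 1.1, 0.4))
  tab <- assign_restriction_table(ranks)
  expect_equal(tab$peptide, c("SLLQHLIGL", "IVDPGYLGY"))
  expect_equal(tab$allele, c("A*02:01", "A*01:01"))
  expect_equal(tab$category, c("SB", "SB"))
})

test_that("the PSSM rank surrogate ranks motif-conforming peptides strongly", {
  model <- motif_a2_like()
  peps <- sample_peptides(model, 300L, c("9" = 1), seed = 13)
  pfm <- build_pfm(peps, pseudocount = 1)
  motif_ranks <- pssm_percent_rank(peps[1:50], pfm, seed = 14)
  random_ranks <- pssm_percent_rank(
    immunopept:::ip_with_seed(15, immunopept:::ip_random_peptides(50, 9L)),
    pfm, seed = 14)
  expect_lt(median(motif_ranks), 5)
  expect_gt(median(random_ranks), 20)
  expect_true(all(motif_ranks >= 0 & motif_ranks <= 100))
})
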