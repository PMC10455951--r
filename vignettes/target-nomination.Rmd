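---
title: "Methods: immunopeptidome, proteome and surfaceome target nomination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunopeptidome, proteome and surfaceome target nomination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopept)
```

`immunopept` implements a desk-scale pipeline for nominating tumor
immunotherapy targets from three mass-spectrometry modalities: HLA class I
immunopeptidomics (which peptides are displayed to CD8+ T cells), global
label-free quantitative (LFQ) proteomics (which proteins are dysregulated
relative to a control tissue), and cell-surface proteomics (which proteins
are accessible to antibodies and CAR constructs). Every analysis stage is
paired with a synthetic-data generator that produces inputs with known
ground truth, so the statistical behaviour of the whole chain can be
verified without access to raw instrument data.

## The peptide filtering ladder

Search-engine output arrives as a peptide-spectrum-match (PSM) table: one
row per fragment spectrum matched to a peptide, with a score, a sample
label, optional modifications and source-protein accessions. The ladder in
`apply_filter_ladder()` turns this into the non-redundant 8–12-mer
immunopeptidome in a fixed order:

1. **FDR cutoff.** q-values are taken from the table or estimated by
   `estimate_q_values()` from target–decoy competition:
   at score threshold $s$, $\widehat{FDR}(s) = \#\{decoys \ge s\} /
   \max(1, \#\{targets \ge s\})$, monotonized from the bottom of the score
   ranking and clipped at 1. The estimator only uses score *ranks*, so it
   is invariant under monotone transforms of the score. PSMs with
   $q > 0.05$ (default) are removed. The FDR is applied at the PSM level;
   peptide-level application is a configuration choice.
2. **Decoy removal** (any survivors of step 1).
3. **Retention-time calibrant removal** — spiked synthetic peptides used
   for chromatographic alignment are contaminants for identification.
4. **Blank removal** — any sequence also detected in a blank run, matched
   on bare sequence (modifications ignored; the simplest defensible
   reading of carryover).
5. **Modified-PSM removal** — the pipeline works on unmodified ligands.
6. **Length restriction** to 8–12 residues, the canonical class I range.
7. **Deduplication** on bare sequence, keeping the highest-scoring PSM and
   merging per-sample maximum intensities.

The retained *set* is provably order-invariant (each predicate is a pure
row property), and the test suite verifies this against a one-pass
set-logic oracle on hundreds of randomized tables; only the per-step
removal counts depend on the order, which is why the report always
satisfies `input = retained + sum(removed)`.

## Motif analysis and HLA restriction

Length distributions and position frequency matrices (PFMs) are computed
by `length_distribution()` and `build_pfm()`. Motif enrichment against a
reference (`icelogo_diff()`) scores each (position, residue) cell by the
percentage-point frequency difference and attaches an exact two-sided
binomial test of the observed count against the reference frequency,
Bonferroni-corrected across all cells. Logo-style tools display
enrichment and depletion separately; at a few thousand peptides the
*depletion* of the 18 non-anchor residues at an anchor position is itself
statistically significant, so anchor recovery is assessed on the
enriched-significant side only (`$enriched`), which for a planted motif is
exactly the set of anchor residues.

Binding strength uses the percent-rank convention of modern class I
predictors: rank ≤ 0.5 is a strong binder (SB), 0.5 < rank ≤ 2.0 a weak
binder (WB), anything else a non-binder. The published interval
definitions overlap at 0.5; the boundary is assigned to the stronger
class, matching the predictor convention that "rank ≤ 0.5" defines strong
binding. `assign_restriction()` gives each peptide the allele with the
minimum rank over the sample's genotype (ties broken by allele name so the
result is deterministic), assigning over both SB and WB by default with an
SB-only mode available. The production path parses external predictor
rank tables (`parse_rank_table()` understands the `%Rank` column dialect);
`pssm_percent_rank()` provides an internal PSSM log-odds surrogate —
the empirical percentile of a peptide's score against a random-peptide
background — so the pipeline runs with no external predictor.

The bundled A3-like generator model places its basic-residue anchors at P1
and the C-terminus, following the anchor-position convention of the
repertoires this generator emulates rather than the textbook P2/P9
pattern; anchor positions are an explicit argument, so either convention
is one call away.

## Spectral validation against synthetic standards

Candidate peptides are confirmed by comparing the endogenous fragment
spectrum with that of a synthesized standard. `theoretical_fragments()`
computes the singly-charged b/y ladder from monoisotopic residue masses
($b_i = \sum_{1..i} m_r + p$, $y_i = \sum_{L-i+1..L} m_r + H_2O + p$);
`match_intensity_vectors()` projects both spectra onto this fragment basis
using a ±0.02 Da window (nearest peak wins; no peak contributes zero), and
`mirror_pearson()` correlates the two intensity vectors. Correlating on
the theoretical-fragment basis rather than raw peak lists makes the score
robust to noise peaks and is how fragmentation-pattern agreement is
assessed in mirror plots. The decision rule in `validate_pair()` is
R ≥ 0.9 by default; the ±3 min retention-time window is implemented but
*off* by default, because the packaged candidate table contains confirmed
peptides whose recorded RT shifts (3.1 and 3.8 min) exceed the window —
an RT rule that strict could not have been binding, so both rules are
exposed and neither intent is guessed.

A zero-variance intensity vector (e.g. no matched fragments) makes the
correlation undefined; this is signalled as a classed condition
(`immunopept_zero_variance`), never as a sentinel value.

## LFQ differential expression

`preprocess_lfq()` log2-transforms and keeps proteins with ≥ 3 valid
values in at least one group. Missingness in LFQ data is
intensity-dependent (missing-not-at-random): low-abundance proteins drop
out. `impute_lfq()` therefore draws each sample's missing entries from
$\mathcal{N}(\bar{x}_s - 1.8\,s_s,\ (0.3\,s_s)^2)$ — a normal distribution
downshifted below that sample's observed distribution. Width 0.3 and
downshift 1.8 are the de-facto standard defaults for this imputation and
are exposed as parameters. `differential_test()` runs a per-protein
two-sided Student t-test (pooled variance; Welch via `var_equal = FALSE`),
Benjamini–Hochberg adjustment, and an up/down/ns call from the
fold-change and adjusted-p cutoffs. Zero-variance ties are resolved by
convention: equal means give p = 1, unequal means give the degenerate
limit p = 0. Row Z-scores (shared by the heatmap exports) use the sample
(n−1) SD, with constant rows mapped to zero.

### Power at the synthetic operating point

The synthetic LFQ testbed plants 100 of 2,000 proteins at |log2 FC| = 2
with within-group SD 0.5 and n = 3 vs 3. It is worth being explicit about
what this design can and cannot detect: the pooled t statistic has 4
degrees of freedom and noncentrality $2/(0.5\sqrt{2/3}) \approx 4.9$, so
the median planted p-value is ≈ 0.006 — yet for BH at 0.05 over 2,000
proteins to recover most of the 100 effects the rejection threshold must
fall near 0.002. The fixed-point sensitivity of this configuration is
therefore only ≈ 0.1 even with complete data, and with so few discoveries
the empirical FDR estimate is dominated by a handful of
downshift-imputation false positives. High sensitivity at this sample
size would require either a variance-moderated (empirical-Bayes) test or
roughly half the within-group SD; the package deliberately keeps the
plain per-protein t-test of the Perseus-style workflow it implements, and
the acceptance suite reports this operating point honestly rather than
tuning the generator to flatter it. The uniformity of null p-values and
FDR control under the global null are verified separately.

## Annotation, set structure and enrichment

`annotate()` joins the retained peptidome against reference databases —
peptide-level (epitope and tumor-antigen collections, joined on exact
sequence) or protein-level (brain-enriched, surface-protein and druggable
collections, joined on *any* source protein, so multi-mapping peptides
inherit the flag). `set_intersections()` produces exclusive
(UpSet-style) intersection counts over up to 12 sample sets: each union
member is counted in exactly one of the $2^k - 1$ combinations, so counts
conserve the union size. `top_shared_matrix()` builds the conserved-
peptide heatmap input: fully-shared rows, ordered by mean log2 intensity,
top k = 40, row Z-scored. `enrich_terms()` is a right-sided
hypergeometric test $P(X \ge x)$ per term with plain Bonferroni by
default; the step-down (Holm) variant is available, but plain Bonferroni
is the more transparent default when no term-level reference numbers are
being matched.

## Surfaceome ranking

`shared_core()` intersects per-cell-line detection sets (a protein counts
as detected in a line if seen in ≥ 1 replicate; configurable).
`tm_filter()` keeps proteins with ≥ 3 predicted transmembrane helices —
helix counts are consumed from an external topology predictor's summary
table, not computed, with a simple simulator standing in for testing.
`rank_surface()` orders the survivors by mean log2 LFQ intensity across
lines (a reference-line ranking was the open alternative; the mean is
used), breaks ties by accession, and attaches surface-marker annotation:
curated surface-database membership, CD-marker naming (`CD` + digits) and
solute-carrier naming (`SLC` prefix) on the gene symbol.

## The synthetic-data module

The generators are pure functions of (parameters, seed) — the global RNG
stream is saved and restored — and their defaults encode the study
conditions the analysis assumes:

* **Repertoires** (`sample_peptides()`): lengths 8–12 with ~65% nonamers;
  anchor positions carry 0.9 probability mass split equally between the
  anchor residues (P2 Leu/Met and C-terminal Leu/Val for the A2-like
  model). Non-nonamers keep absolute anchor positions except the
  C-terminal anchor, which follows the new C-terminus.
* **PSM contamination** (`make_psm_dataset()`): decoys are
  composition-preserving shuffles flagged `DECOY_`, drawn from a score
  distribution stochastically below the true one (normal means 18 vs 30,
  SD 5); 11 fixed synthetic calibrant sequences; blank-carryover peptides
  emitted both in the table and the blank set; modified duplicates clone a
  true PSM with one modification.
* **Spectrum pairs** (`simulate_spectrum_pair()`): base fragment
  intensities are drawn log-normal (sdlog = 1) once per pair and perturbed
  independently per spectrum by multiplicative log-normal noise of the
  requested CV, so the mirror correlation is exactly 1 at CV = 0 and
  degrades smoothly with noise; random noise peaks are kept out of the
  ±0.02 Da fragment windows so they only test robustness of the basis
  projection, not matching luck.
* **LFQ experiments** (`simulate_lfq_experiment()`): baseline log2
  abundances N(25, 2), within-group SD 0.5, logistic MNAR dropout with
  midpoint 21 and unit steepness (≈ 10–15% missing, concentrated at low
  abundance), effects of random sign in the first group.

What the generators do **not** emulate: chromatographic peak shapes,
isotope envelopes, multiply-charged fragments, correlated protein
abundances, batch effects, or shared-peptide protein inference. Green
tests therefore demonstrate the correctness of the statistical machinery
on data satisfying the stated assumptions — not robustness to every
pathology of real instrument output.

## Numerical choices and degenerate inputs

* Retention time is minutes everywhere internally; MGF `RTINSECONDS` is
  converted on read.
* Modifications are encoded `"pos|Name"`, semicolon-joined — unambiguous
  and round-trippable.
* Duplicate (peptide, allele) rank rows collapse to the minimum rank.
* Empty PSM input to the ladder yields an all-zero report, not an error;
  an empty annotation *database* is an error (always a configuration
  mistake).
* `estimate_q_values()` requires at least one target and one decoy and
  handles tied scores by evaluating counts at the last row of each tie
  group.
* All pipeline outputs are stamped with the seed and an FNV-1a hash of
  the configuration, and `run_pipeline()` is byte-deterministic given
  (config, seed).

## Problem sizes in the test suite

The suite exercises the ladder/oracle equivalence on 1,000 randomized
tables, spectral discrimination on 200 same-peptide and 200 mismatched
pairs, motif recovery on a 2,000-peptide repertoire, DE recovery on ten
2,000 × 6 experiments, and set/enrichment machinery against exhaustive
enumeration for backgrounds small enough to enumerate (up to ~3,000
combinations). These sizes give binomial standard errors comfortably
inside every asserted tolerance while keeping the full suite under a
minute.
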