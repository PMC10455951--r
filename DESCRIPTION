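Package: immunopept
Title: Immunopeptidome, Proteome and Surfaceome Target Nomination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for nominating tumor immunotherapy targets
    from HLA class I immunopeptidomics, label-free quantitative proteomics and
    cell-surface proteomics. Implements the peptide-spectrum-match filtering
    ladder (target-decoy q-values, decoy/iRT/blank/modification removal,
    8-12-mer length restriction, deduplication), peptide length and binding-motif
    analysis with logo-style enrichment statistics, percent-rank based HLA
    restriction assignment (strong/weak binder classification), b/y fragment-ion
    spectral validation against synthetic peptide standards (mirror Pearson
    correlation with a retention-time window), a Perseus-style label-free
    quantification workflow (log2 transform, valid-value filtering, downshifted
    normal imputation, two-sample t-tests with BH correction, volcano and
    Z-score tables), annotation against peptide- and protein-level reference
    databases with exclusive set-intersection (UpSet) counting and
    hypergeometric term enrichment, and transmembrane-helix based surfaceome
    ranking. A synthetic-data module generates motif-structured peptide
    repertoires, contaminated PSM tables, paired endogenous/synthetic spectra
    and missing-not-at-random LFQ matrices with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
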