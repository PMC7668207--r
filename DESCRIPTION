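Package: asnscreen
Title: Immunogenicity Screening of Therapeutic L-Asparaginase Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based triage of candidate therapeutic enzymes
    (L-asparaginases) by predicted MHC class II immunogenicity. Provides
    redundancy clustering of protein sequences at an identity cutoff,
    conserved-motif scanning for family assignment, 15-mer peptide
    windowing with additive pocket-profile (TEPITOPE-style) scoring per
    HLA-DRB1 allele, percentile-rank calibration against random peptide
    backgrounds, consensus percentile ranks, 9-mer core extraction, an
    epitope-density statistic, allele coverage, per-residue epitope maps,
    and Pareto-based candidate ranking against a reference enzyme. A
    synthetic-data module generates proteomes with planted binder cores,
    homolog families of controlled identity, and screening tables with
    known extrema, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
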