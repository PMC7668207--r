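---
title: "Screening candidate enzymes for MHC class II immunogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate enzymes for MHC class II immunogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asnscreen)
```

## The screening problem

Therapeutic proteins of microbial origin — here, L-asparaginases used
against acute lymphoblastic leukemia — provoke anti-drug immune responses
driven largely by CD4+ T-cell help, which requires peptides from the
protein to be presented on MHC class II. A protein whose sequence yields
fewer, weaker MHC-II binding peptides across common HLA alleles is a
plausibly less immunogenic drug candidate. `asnscreen` turns that idea into
a pipeline: reduce a homolog set to non-redundant representatives, label
their enzyme family by conserved motifs, enumerate candidate T-cell
epitopes per HLA-DRB1 allele, condense them into per-protein statistics,
and rank candidates against the clinical reference enzyme.

## Model and assumptions

**Peptide unit.** MHC-II binding is screened on overlapping 15-mers
(`window_peptides`), the conventional scanning unit; the groove itself
seats a 9-mer register, so each window is scored as the best of its seven
9-mer frames (`score_window`, ties to the smallest offset for determinism).

**Scoring.** The in-package scorer is an additive pocket-profile matrix: 9
positions x 20 residues of real-valued binding contributions
(`pocket_profile`, `score_core`). Additivity over positions is the standard
TEPITOPE-style approximation; it ignores inter-position coupling. Neural
and stabilised-matrix predictors are deliberately out of scope — their
percentile exports can instead be ingested (`read_prediction_table`) and
enter the consensus.

**Percentile ranks.** Raw scores are allele- and matrix-specific, so they
are calibrated to percentile ranks against the score distribution of random
peptides (`make_background`, `calibrate_percentile`): the percentile is the
percentage of background peptides scoring *strictly* better, so 0 is the
best possible rank, ties never penalise the query, and the rank is
monotone in the raw score. Lower percentile = stronger predicted binder.
Backgrounds are drawn residue-wise from a stated frequency model (uniform
by default; a Swiss-Prot-like composition is available via
`aa_frequencies("swissprot")`) and are a pure function of (matrix, n, k,
frequencies, seed).

**Consensus.** Per (window, allele) the consensus percentile rank (CPR) is
the median over available methods (`consensus_rank`); with only the
pocket-profile method configured the CPR is its percentile. When a method
lacks coverage for an allele the median is taken over the methods present —
coverage is recorded in `n_methods` rather than imputed.

**Thresholds.** Windows with CPR < 2 count as high-affinity binders; a
window's best 9-mer core is retained only if the core's *own* percentile
(scored directly against a 9-mer background) is < 1 (`extract_cores`).
Scoring the core itself, rather than reusing the parent window's rank, was
a genuinely open choice; we score the core because the retained object is
the core and the 15-mer rank mixes in flanking-frame information. Cores
reached from several overlapping windows are reported once per (protein,
allele, start) — this is the main guard against over-counting epitopes in
overlapping windows.

**Per-protein statistics.** (`build_screening_row`)

* epitope count: distinct (core sequence, start) pairs pooled across
  alleles — a core presented by several alleles is one epitope;
* allele coverage: number of distinct panel alleles with at least one
  retained core (`allele_coverage`) — the population-reactivity proxy;
* affinity average: mean over counted epitopes of each epitope's minimum
  core CPR across alleles (one value per epitope, favouring its strongest
  allele);
* epitope density:
  `ED = count * (2 - mean_CPR) / (length - epitope_size + 1)`
  (`epitope_density`). The numerator weights each epitope by how far below
  the binder threshold its affinity sits; the denominator normalises by the
  number of epitope-sized windows the protein offers. `epitope_size`
  defaults to 9 because the counted unit is the 9-mer core; it is
  configurable to 15 if whole windows are counted instead.

**Ranking.** Candidates are compared on (ED, allele coverage, antigenicity
probability), all "lower is better", with no weighting: `select_candidates`
returns the Pareto front (exhaustively checked dominance), optionally
restricted to one family. Antigenicity probabilities are consumed as an
external score table (`read_antigenicity`); the package does not compute
them. The reference enzyme anchors the comparison and is never selected.

## Intake, identity, and clustering

Identity between two sequences is the number of identical positions in an
optimal global alignment divided by the shorter sequence's length —
CD-HIT's denominator convention — with match +1, mismatch 0, gap -0.5 and
free end gaps (`pairwise_identity`, via `Biostrings::pairwiseAlignment`).
Ambiguity codes (X/B/Z/U) are rejected at intake by default; when admitted
they never count as identical positions and never satisfy fixed motif
positions, though they do match motif wildcards — conservative on both
fronts. Clustering (`greedy_cluster`) is greedy incremental: sequences
sorted longest-first (ties by id, C-locale) join the first representative
at or above the cutoff (default 0.6), else found a new cluster; this makes
the partition deterministic and gives the representative-separation
invariant checked in the tests.

Default intake length bounds are 316–428 residues: the extremes actually
present in the packaged representative table. (Its accompanying prose says
"320 to 420", which contradicts the table's own entries; we follow the
table.)

## Family motifs

Profile-HMM family assignment is out of scope; `assign_family` labels a
protein by which family's signature motifs hit it more often. The
PF06089.11 signatures are the conserved motifs of that family
(`NCSGKHxAM`, `DGCGAPL`, `SHSGEx(2)H`, `PRSx(2)KPxQ`). The PF00710.11
entries (`TGGTxAGG`, `HGTDTM`) are proxies built from the catalytic
threonine context of the *E. coli* type-II enzyme — adequate for labelling
clean sequences, not for remote homology detection. Motif notation:
uppercase fixed residues, `x` any residue, `x(n)` a wildcard run; all
coordinates are 1-based inclusive and every reported hit re-slices the
sequence exactly.

## The synthetic-data module

`generate_proteome` emulates the screened length regime (300–430 residue
proteins) with residues drawn from a stated frequency model and binder
cores spliced in place (overwriting, so lengths are unchanged) at known
(protein, allele, start) positions. `generate_pssm` builds matrices whose
favoured core sits a chosen number of standard deviations above the random
9-mer score distribution — at the default contrast the core outscores the
entire calibration background, making planted-core recovery an exact
expectation. `generate_homolog_family` derives members from one ancestor by
per-site substitution to a different residue, giving expected pairwise
identity `(1-r)^2 + r^2/(k-1)`; families at rate 0.1 sit far above the 0.6
clustering cutoff, unrelated random sequences far below.
`generate_screening_table` plants unique ED extrema at known ids. All
generators are pure functions of their spec and seed.

What the synthetic data does **not** emulate: real amino-acid composition
biases and local sequence correlation, homology between proteome members,
indel evolution, and true MHC binding chemistry (the planted signal is an
idealised additive binder). Passing the planted-recovery tests therefore
shows the pipeline's bookkeeping and calibration are correct, not that the
pocket-profile scorer predicts real epitopes — real-data accuracy is
inherited from whatever matrices or external method tables the user
supplies.

A consequence of percentile calibration worth knowing: at the CPR < 2 /
core < 1 thresholds, about 0.3–0.5% of window-allele pairs in *random*
sequence are retained as chance cores (the calibration tail). The
validation benchmark (`planted_epitope_benchmark`) is designed around this
noise floor: 10 proteins, a 2-allele panel, and 14 planted cores per
positive protein (the density of the most epitope-rich enzyme in the
packaged table), which separates planted proteins from the background-only
control by several noise standard deviations in ED.

## Numerical and design choices

* Percentile = 100 x (strictly greater) / n; exact 0 and 100 at the
  extremes; `findInterval` on the sorted background for O(log n) queries.
* Median with even method counts = mean of the two central order
  statistics (`stats::median`).
* Frame ties in `score_window` and greedy-order ties in clustering resolve
  to the smallest offset / lexicographically first id: every run is
  deterministic given inputs and seed.
* Background size defaults to 100000 (configurable); percentile
  granularity 0.001 is ample for thresholds at 1 and 2. Tests and the
  acceptance benchmark use 2000–20000 so the full suite runs in seconds;
  at 20000 the granularity at the 1% threshold is 0.005 percentile points.
* The packaged screening table's printed ED values are *not* reproducible
  from its printed epitope numbers, CPR values, and lengths under the ED
  formula (no plausible length makes 10 x (2 - 0.6383) / (L - 8) equal
  0.0114). `load_screening_table` therefore treats printed ED as opaque
  data and reports the recomputation mismatch as a warning, never an
  error. One reference row (the ScAII homolog) has no packaged length, so
  its recomputation is skipped.
* The published selection of low-immunogenicity candidates excludes the
  lowest-ED enzyme without an explicit rule; the package exposes the
  machinery it implies — Pareto dominance plus an optional family
  restriction (`restrict_family = "PF06089.11"`) — and flags the
  restriction as interpretation rather than hard-coding the outcome.
* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state; derived per-allele seeds stay below 2^31.

## Limitations

* Only the pocket-profile scorer is implemented; consensus quality with a
  single method is just that method. External predictors participate only
  through exported percentile tables.
* Motif-based family labels are heuristics; genuinely novel sequences can
  come back `unassigned` or `ambiguous`.
* Identity uses one fixed scoring scheme; it reproduces CD-HIT semantics
  but not its word-filter speed — clustering is quadratic in set size and
  meant for hundreds, not millions, of sequences.
* ED compares candidates on predicted epitope content only; it is not a
  claim about in-vivo immunogenicity, and antigenicity inputs are trusted
  as given.
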