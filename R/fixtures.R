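# Accessors for the packaged reference tables.

#' Representative asparaginase table
#'
#' The packaged table of representative Streptomyces asparaginases obtained
#' at a 60% identity cutoff: accession, organism, length, and family
#' (PF00710.11 or PF06089.11).
#'
#' @return `data.frame` with columns `id`, `organism`, `length`, `family`.
#' @export
asn_table1 <- function() {
  df <- .read_tsv(system.file("extdata", "table1.tsv", package = "asnscreen",
                              mustWork = TRUE),
                  required = c("id", "organism", "length", "family"))
  df$length <- as.integer(df$length)
  df
}

#' Packaged high-affinity epitope screening table
#'
#' The packaged per-protein screening summary (epitope number, affinity
#' average CPR, allele coverage, ED) for the representative asparaginases
#' plus the E. coli (P00805_EcAII) and S. coelicolor (Q9K4F5_ScAII)
#' references. Printed ED values are carried verbatim; they are not
#' reproducible from the printed epitope numbers, CPR values, and lengths
#' under the ED formula, so [load_screening_table()] reports the discrepancy
#' as a warning and keeps the printed values.
#'
#' @param lengths Representative table used to join lengths; default
#'   [asn_table1()]. Pass `NULL` to skip the join and the formula check.
#' @param ... Passed to [load_screening_table()] (e.g. `check_formula`).
#' @return Screening `data.frame` (26 rows); see [load_screening_table()].
#' @export
asn_table2 <- function(lengths = asn_table1(), ...) {
  load_screening_table(system.file("extdata", "table2.tsv",
                                   package = "asnscreen", mustWork = TRUE),
                       lengths = lengths, ...)
}

#' The eight-allele HLA-DRB1 screening panel
#'
#' The HLA class II allele panel used for epitope screening; together these
#' alleles represent over 95% of the world population.
#'
#' @return Character vector of eight HLA-DRB1 allele names.
#' @export
hla_panel <- function() {
  c("HLA-DRB1*01:01", "HLA-DRB1*03:01", "HLA-DRB1*04:01", "HLA-DRB1*07:01",
    "HLA-DRB1*08:01", "HLA-DRB1*11:01", "HLA-DRB1*13:01", "HLA-DRB1*15:01")
}
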