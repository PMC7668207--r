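# Per-protein screening statistics: epitope density, allele coverage,
# per-residue epitope maps, and the screening summary table.

#' Epitope density
#'
#' The immunogenicity statistic used to compare candidate enzymes:
#'
#'   ED = epitope_count * (2 - mean_cpr) / (length - epitope_size + 1)
#'
#' where `epitope_count` is the number of retained epitopes (CPR < 1 cores),
#' `mean_cpr` their average consensus percentile rank, and the denominator
#' the number of epitope-sized windows the protein offers. Lower ED predicts
#' lower immunogenicity.
#'
#' @param epitope_count Non-negative integer count of retained epitopes.
#' @param mean_cpr Average CPR of the counted epitopes, in `[0, 2)`.
#' @param length Protein length in residues.
#' @param epitope_size Size of the counted epitope unit (default 9, the
#'   MHC-II core length; 15 counts whole windows instead).
#' @return Non-negative epitope density; 0 exactly when `epitope_count` is 0.
#' @export
#' @examples
#' epitope_density(5, 0.5, 350)  # 5 * 1.5 / 342
epitope_density <- function(epitope_count, mean_cpr, length,
                            epitope_size = 9L) {
  if (any(length < epitope_size)) {
    stop("protein length must be >= epitope_size", call. = FALSE)
  }
  if (any(epitope_count < 0)) stop("epitope_count must be >= 0", call. = FALSE)
  if (any(epitope_count > 0 & (mean_cpr < 0 | mean_cpr >= 2))) {
    stop("mean_cpr must lie in [0, 2)", call. = FALSE)
  }
  ifelse(epitope_count == 0, 0,
         epitope_count * (2 - mean_cpr) / (length - epitope_size + 1))
}

#' Allele coverage of a protein's retained cores
#'
#' Number of distinct HLA alleles with at least one retained high-affinity
#' core — a proxy for the fraction of the population potentially reactive.
#'
#' @param cores Core table (rows of one protein) from [extract_cores()].
#' @return Integer count of distinct alleles (0 for an empty table).
#' @export
allele_coverage <- function(cores) {
  if (!nrow(cores)) return(0L)
  if (length(unique(cores$protein_id)) > 1L) {
    stop("cores must belong to a single protein", call. = FALSE)
  }
  length(unique(cores$allele))
}

#' Per-residue epitope density map
#'
#' Counts, for every residue, how many retained (core, allele) instances
#' cover it — the per-position hit counts behind epitope-map heatmaps.
#'
#' @param cores Core table for one protein.
#' @param length Protein length in residues.
#' @param core_size Core span (default 9).
#' @return Integer vector of length `length`; its sum equals
#'   `core_size * nrow(cores)`.
#' @export
density_map <- function(cores, length, core_size = 9L) {
  counts <- integer(length)
  if (!nrow(cores)) return(counts)
  if (any(cores$start < 1L | cores$start + core_size - 1L > length)) {
    stop("core span outside the protein", call. = FALSE)
  }
  for (i in seq_len(nrow(cores))) {
    span <- cores$start[i]:(cores$start[i] + core_size - 1L)
    counts[span] <- counts[span] + 1L
  }
  counts
}

#' Summarise one protein's retained cores into a screening row
#'
#' Epitopes are counted as distinct (core sequence, start) pairs pooled
#' across alleles — a core retained for several alleles is one epitope, with
#' the multiplicity expressed through allele coverage. The affinity average
#' is the mean, over counted epitopes, of each epitope's best (minimum) core
#' CPR across alleles.
#'
#' @param protein Single protein record row.
#' @param cores Core table for this protein from [extract_cores()].
#' @param epitope_size Epitope unit for the ED denominator (default 9).
#' @return One-row `data.frame`: `id`, `epitope_count`, `mean_cpr`,
#'   `allele_count`, `length`, `ed`.
#' @export
build_screening_row <- function(protein, cores, epitope_size = 9L) {
  stopifnot(nrow(protein) == 1L)
  if (nrow(cores)) {
    if (any(cores$protein_id != protein$id)) {
      stop("cores must belong to protein ", protein$id, call. = FALSE)
    }
    if (any(cores$core_cpr >= 1)) {
      stop("retained cores must have core_cpr < 1", call. = FALSE)
    }
    key <- paste(cores$core, cores$start, sep = "\r")
    best <- tapply(cores$core_cpr, key, min)
    epitope_count <- length(best)
    mean_cpr <- mean(best)
    allele_count <- allele_coverage(cores)
  } else {
    epitope_count <- 0L
    mean_cpr <- 0
    allele_count <- 0L
  }
  data.frame(id = protein$id,
             epitope_count = as.integer(epitope_count),
             mean_cpr = mean_cpr,
             allele_count = as.integer(allele_count),
             length = protein$length,
             ed = epitope_density(epitope_count, mean_cpr, protein$length,
                                  epitope_size),
             stringsAsFactors = FALSE)
}

#' Screening table for a set of proteins
#'
#' @param records Protein record table.
#' @param cores Core table from [extract_cores()] (any proteins).
#' @param epitope_size Epitope unit for the ED denominator (default 9).
#' @return `data.frame` of screening rows, one per protein, in record order.
#' @export
build_screening_table <- function(records, cores, epitope_size = 9L) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- records[i, , drop = FALSE]
    build_screening_row(p, cores[cores$protein_id == p$id, , drop = FALSE],
                        epitope_size)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Rename internal screening columns to the on-disk dialect
# (id, epitope_number, cpr_value, allele_number, ed [, length]).
.screening_to_dialect <- function(df) {
  out <- df[c("id", "epitope_count", "mean_cpr", "allele_count", "ed",
              "length")]
  names(out) <- c("id", "epitope_number", "cpr_value", "allele_number",
                  "ed", "length")
  out
}

#' Write a screening table in the interchange dialect
#'
#' Writes columns `id`, `epitope_number`, `cpr_value`, `allele_number`,
#' `ed`, `length`, readable back by [load_screening_table()].
#'
#' @param rows Screening table from [build_screening_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_screening_table <- function(rows, path) {
  .write_tsv(.screening_to_dialect(rows), path)
}

#' Load a screening summary table
#'
#' Reads an externally produced screening table (id, epitope number, CPR
#' value, allele number, ED). When a representative table with lengths is
#' supplied, lengths are joined (accession versions ignored) and each printed
#' ED is checked against the ED formula; disagreements are reported as
#' warnings, never errors, and the printed values are kept.
#'
#' @param path TSV with columns `id`, `epitope_number`, `cpr_value`,
#'   `allele_number`, `ed`.
#' @param lengths Optional `data.frame` with columns `id` and `length`
#'   (e.g. [asn_table1()]).
#' @param check_formula Verify printed ED against the formula when a length
#'   is available (default `TRUE`).
#' @return `data.frame` with columns `id`, `epitope_count`, `mean_cpr`,
#'   `allele_count`, `ed`, and `length` (NA where unknown).
#' @export
load_screening_table <- function(path, lengths = NULL, check_formula = TRUE) {
  df <- .read_tsv(path, required = c("id", "epitope_number", "cpr_value",
                                     "allele_number", "ed"))
  if (!nrow(df)) stop("screening table is empty: ", path, call. = FALSE)
  out <- data.frame(id = as.character(df$id),
                    epitope_count = as.integer(df$epitope_number),
                    mean_cpr = as.numeric(df$cpr_value),
                    allele_count = as.integer(df$allele_number),
                    ed = as.numeric(df$ed),
                    length = if ("length" %in% names(df))
                      as.integer(df$length) else NA_integer_,
                    stringsAsFactors = FALSE)
  if (any(out$epitope_count < 0) || any(out$allele_count < 0)) {
    stop("negative counts in screening table: ", path, call. = FALSE)
  }
  if (any(out$ed < 0)) stop("negative ED in screening table: ", path,
                            call. = FALSE)
  if (!is.null(lengths)) {
    idx <- match(.strip_version(out$id), .strip_version(lengths$id))
    fill <- is.na(out$length)
    out$length[fill] <- lengths$length[idx[fill]]
    if (check_formula) {
      have <- which(!is.na(out$length) & out$mean_cpr < 2)
      recomputed <- epitope_density(out$epitope_count[have],
                                    out$mean_cpr[have], out$length[have])
      off <- abs(recomputed - out$ed[have]) > 5e-4
      if (any(off)) {
        warning(sprintf("printed ED differs from the ED formula for %d row(s) (e.g. %s: printed %.4f vs recomputed %.4f); printed values kept",
                        sum(off), out$id[have][off][1L],
                        out$ed[have][off][1L], recomputed[off][1L]),
                call. = FALSE)
      }
    }
  }
  out
}

#' Proteins with higher epitope density than a reference
#'
#' @param rows Screening table (from [build_screening_table()] or
#'   [load_screening_table()]).
#' @param reference_id Id of the reference protein (must be present).
#' @return Character vector of ids with ED strictly greater than the
#'   reference's, sorted by descending ED.
#' @export
compare_to_reference <- function(rows, reference_id) {
  i <- match(reference_id, rows$id)
  if (is.na(i)) stop("reference id not found: ", reference_id, call. = FALSE)
  ref_ed <- rows$ed[i]
  above <- rows[rows$ed > ref_ed & rows$id != reference_id, , drop = FALSE]
  above$id[order(-above$ed, above$id, method = "radix")]
}

#' Read an antigenicity score table
#'
#' Per-protein predicted probabilities of antigenicity produced by an
#' external sequence-based predictor; consumed as a ranking criterion.
#'
#' @param path TSV with columns `id`, `probability`.
#' @return `data.frame` with `id` and `probability` in `[0, 1]`.
#' @export
read_antigenicity <- function(path) {
  df <- .read_tsv(path, required = c("id", "probability"))
  df$probability <- as.numeric(df$probability)
  if (any(is.na(df$probability) | df$probability < 0 | df$probability > 1)) {
    stop("antigenicity probabilities must lie in [0, 1]: ", path,
         call. = FALSE)
  }
  df[c("id", "probability")]
}
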