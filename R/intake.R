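# Sequence intake: FASTA reading, validation, and length/ambiguity filtering.

#' Read protein sequences from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file into a protein
#' record table. Sequences are normalised to uppercase; the record id is the
#' first whitespace-delimited token of the header, the remainder becomes the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `description`, `sequence`,
#'   `length`, one row per FASTA entry in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "ACDEF"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  .check_string(path, "path")
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    stop("FASTA format error: file is empty: ", path, call. = FALSE)
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("FASTA format error at line %d: expected '>' header", first),
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (!length(set)) {
    stop("FASTA format error: no records in ", path, call. = FALSE)
  }
  headers <- names(set)
  if (any(!nzchar(trimws(headers)))) {
    bad <- which(!nzchar(trimws(headers)))[1L]
    stop(sprintf("FASTA format error: empty header for record %d", bad),
         call. = FALSE)
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1L), 1L)
  desc <- trimws(sub("^\\S+\\s*", "", headers))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(sprintf("FASTA format error: record '%s' has an empty sequence",
                 ids[which(empty)[1L]]), call. = FALSE)
  }
  protein_records(id = ids, description = desc, sequence = seqs)
}

#' Construct a protein record table
#'
#' Builds the `data.frame` representation used throughout the package, with
#' the invariant `length == nchar(sequence)` enforced. Sequences may contain
#' only canonical residues plus the ambiguity codes X/B/Z/U (screened later by
#' [filter_records()]).
#'
#' @param id Character vector of accession-like identifiers.
#' @param sequence Character vector of amino-acid sequences (uppercased).
#' @param description Optional character vector of free-text descriptions.
#' @return A `data.frame` with columns `id`, `description`, `sequence`, `length`.
#' @export
protein_records <- function(id, sequence, description = "") {
  if (length(id) != length(sequence)) {
    stop("id and sequence must have equal length", call. = FALSE)
  }
  sequence <- toupper(sequence)
  ok <- grepl(sprintf("^[%s]+$",
                      paste(c(aa_alphabet(), AA_AMBIGUOUS), collapse = "")),
              sequence)
  if (any(!ok)) {
    stop(sprintf("record '%s' contains non-amino-acid characters",
                 id[which(!ok)[1L]]), call. = FALSE)
  }
  data.frame(id = as.character(id),
             description = rep_len(as.character(description), length(id)),
             sequence = sequence,
             length = nchar(sequence),
             stringsAsFactors = FALSE)
}

#' Filter protein records by length and residue content
#'
#' Screens out partial or out-of-range sequences before clustering and epitope
#' prediction. Default bounds span the representative candidate set (316-428
#' residues). Records are never dropped silently: each rejected record carries
#' a machine-readable reason.
#'
#' @param records Protein record table from [read_fasta()].
#' @param min_length,max_length Inclusive residue-count bounds.
#' @param reject_ambiguous If `TRUE` (default), records containing X/B/Z/U are
#'   rejected with reason `ambiguous_residues`.
#' @return A list with elements `kept` (record table) and `rejected` (record
#'   table with an extra `reason` column: `too_short`, `too_long`, or
#'   `ambiguous_residues`).
#' @export
filter_records <- function(records, min_length = 316L, max_length = 428L,
                           reject_ambiguous = TRUE) {
  if (min_length > max_length) {
    stop("min_length must be <= max_length", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(records))
  reason[records$length < min_length] <- "too_short"
  reason[records$length > max_length] <- "too_long"
  if (reject_ambiguous) {
    amb <- is.na(reason) & !vapply(records$sequence, .is_canonical, logical(1L))
    reason[amb] <- "ambiguous_residues"
  }
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
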