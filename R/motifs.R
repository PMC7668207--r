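# Conserved-motif scanning and family assignment.
#
# Motifs are written in the compact notation used for asparaginase family
# signatures: uppercase one-letter residues are fixed positions, lowercase
# "x" is any residue, and "x(n)" expands to n wildcards (e.g. "SHSGEx(2)H").

#' Compile a motif pattern
#'
#' Parses the fixed-residue / wildcard notation into a positional pattern.
#'
#' @param name Motif name.
#' @param notation Pattern string: uppercase residues, `x` wildcards,
#'   `x(n)` for n consecutive wildcards.
#' @return An object of class `motif_pattern` with fields `name`, `notation`,
#'   `tokens` (character vector, one per position, `"x"` marking wildcards)
#'   and `span`.
#' @export
#' @examples
#' compile_motif("site_B", "SHSGEx(2)H")
compile_motif <- function(name, notation) {
  .check_string(name, "name")
  .check_string(notation, "notation")
  tokens <- character(0)
  rest <- notation
  while (nzchar(rest)) {
    ch <- substr(rest, 1L, 1L)
    if (ch %in% aa_alphabet()) {
      tokens <- c(tokens, ch)
      rest <- substring(rest, 2L)
    } else if (ch == "x") {
      rest <- substring(rest, 2L)
      n <- 1L
      if (startsWith(rest, "(")) {
        close <- regexpr(")", rest, fixed = TRUE)
        if (close < 0L) {
          stop("motif parse error in '", notation, "': unclosed repeat",
               call. = FALSE)
        }
        num <- substr(rest, 2L, close - 1L)
        if (!grepl("^[0-9]+$", num) || as.integer(num) < 1L) {
          stop("motif parse error in '", notation,
               "': repeat count must be a positive integer", call. = FALSE)
        }
        n <- as.integer(num)
        rest <- substring(rest, close + 1L)
      }
      tokens <- c(tokens, rep("x", n))
    } else {
      stop("motif parse error in '", notation, "': unexpected character '",
           ch, "'", call. = FALSE)
    }
  }
  if (!length(tokens)) {
    stop("motif parse error: empty pattern '", notation, "'", call. = FALSE)
  }
  structure(list(name = name, notation = notation,
                 tokens = tokens, span = length(tokens)),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (span %d)\n", x$name, x$notation, x$span))
  invisible(x)
}

#' Canonical notation of a compiled motif
#'
#' Re-serialises the token list, collapsing wildcard runs back to `x(n)`.
#'
#' @param pattern A `motif_pattern`.
#' @return The canonical notation string.
#' @export
motif_notation <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  r <- rle(pattern$tokens == "x")
  pos <- cumsum(c(1L, r$lengths))
  parts <- mapply(function(is_x, len, at) {
    if (!is_x) paste(pattern$tokens[at:(at + len - 1L)], collapse = "")
    else if (len == 1L) "x" else sprintf("x(%d)", len)
  }, r$values, r$lengths, pos[seq_along(r$values)])
  paste(parts, collapse = "")
}

#' Scan a protein for motif occurrences
#'
#' Reports every (possibly overlapping) occurrence of each pattern with
#' 1-based inclusive coordinates. Wildcard positions match any residue,
#' including ambiguity codes; fixed positions match only the stated canonical
#' residue (so ambiguity codes never satisfy a fixed position).
#'
#' @param record Single protein record row (or a record table; all rows are
#'   scanned).
#' @param patterns A `motif_pattern` or list of them.
#' @return A `data.frame` with columns `protein_id`, `motif_name`, `start`,
#'   `end`, `matched` (empty when there are no hits).
#' @export
scan_motifs <- function(record, patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  stopifnot(all(vapply(patterns, inherits, logical(1L), "motif_pattern")))
  hits <- list()
  for (r in seq_len(nrow(record))) {
    res <- .residues(record$sequence[r])
    for (p in patterns) {
      span <- p$span
      if (length(res) < span) next
      fixed <- which(p$tokens != "x")
      for (s in seq_len(length(res) - span + 1L)) {
        window <- res[s:(s + span - 1L)]
        if (all(window[fixed] == p$tokens[fixed])) {
          hits[[length(hits) + 1L]] <- data.frame(
            protein_id = record$id[r], motif_name = p$name,
            start = s, end = s + span - 1L,
            matched = paste(window, collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(protein_id = character(0), motif_name = character(0),
                      start = integer(0), end = integer(0),
                      matched = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Assign a protein to an asparaginase family by motif content
#'
#' A lightweight stand-in for profile-HMM family assignment: the protein is
#' labelled with the family whose signature motifs hit it most often.
#'
#' @param record Single protein record row.
#' @param pf00710_patterns,pf06089_patterns Non-empty lists of
#'   `motif_pattern`s characteristic of each family.
#' @return `"PF00710.11"`, `"PF06089.11"`, `"unassigned"` (no hits), or
#'   `"ambiguous"` (tied hit counts).
#' @export
assign_family <- function(record, pf00710_patterns, pf06089_patterns) {
  if (!length(pf00710_patterns) || !length(pf06089_patterns)) {
    stop("both family pattern sets must be non-empty", call. = FALSE)
  }
  n710 <- nrow(scan_motifs(record, pf00710_patterns))
  n089 <- nrow(scan_motifs(record, pf06089_patterns))
  if (n710 == 0L && n089 == 0L) return("unassigned")
  if (n710 == n089) return("ambiguous")
  if (n710 > n089) "PF00710.11" else "PF06089.11"
}

#' Read a motif definition table
#'
#' @param path TSV with columns `name`, `notation`, `family`.
#' @return Named list of compiled `motif_pattern`s, with a `family` attribute
#'   (character vector parallel to the list).
#' @export
read_motif_table <- function(path) {
  df <- .read_tsv(path, required = c("name", "notation", "family"))
  pats <- mapply(compile_motif, df$name, df$notation, SIMPLIFY = FALSE)
  names(pats) <- df$name
  attr(pats, "family") <- df$family
  pats
}

#' Packaged asparaginase family signature motifs
#'
#' The conserved PF06089.11 signatures (NCSGKHxAM, DGCGAPL, SHSGEx(2)H,
#' PRSx(2)KPxQ) plus proxy PF00710.11 patterns drawn from the catalytic
#' threonine context of the E. coli type-II enzyme (TGGTxAGG, HGTDTM). The
#' PF00710 entries are motif proxies for profile-based family calls, adequate
#' for labelling, not for remote homology detection.
#'
#' @return Named list of `motif_pattern`s with a `family` attribute.
#' @export
asn_family_motifs <- function() {
  read_motif_table(system.file("extdata", "family_motifs.tsv",
                               package = "asnscreen", mustWork = TRUE))
}
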