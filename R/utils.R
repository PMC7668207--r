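# Internal helpers shared across modules.

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter codes for the canonical amino acids, in the conventional
#' alphabetical order used by scoring-matrix files.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
}

# Ambiguity / non-canonical codes tolerated at intake when permitted.
AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' Background amino-acid frequencies
#'
#' Residue frequencies used when sampling random peptides for percentile
#' calibration and synthetic proteomes. `"uniform"` gives 1/20 per residue;
#' `"swissprot"` gives the overall composition of the Swiss-Prot knowledgebase
#' (UniProtKB release statistics), so backgrounds resemble peptides drawn at
#' random from a curated proteome.
#'
#' @param model `"uniform"` or `"swissprot"`.
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
aa_frequencies <- function(model = c("uniform", "swissprot")) {
  model <- match.arg(model)
  if (model == "uniform") {
    f <- rep(1 / 20, 20)
    names(f) <- aa_alphabet()
    return(f)
  }
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86,
         G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
         M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
         S = 6.64, T = 5.35, W = 1.10, Y = 2.92, V = 6.86)
  f <- f[aa_alphabet()]
  f / sum(f)
}

# Assert a single non-empty character scalar.
.check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("%s must be a non-empty string", what), call. = FALSE)
  }
  invisible(x)
}

# Split a sequence string into a character vector of residues.
.residues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# TRUE if the sequence contains only the 20 canonical residues.
.is_canonical <- function(seq) {
  !grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), seq)
}

# Strip a trailing ".<digits>" accession version for cross-table joins.
.strip_version <- function(id) sub("\\.\\d+$", "", id)

# Read a TSV with required columns; errors name the missing ones.
.read_tsv <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
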