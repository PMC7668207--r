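# Pocket-profile scoring matrices: the additive 9-position x 20-residue
# weights (TEPITOPE / Sturniolo style) used as the in-package MHC-II scorer.

#' Construct a pocket-profile matrix
#'
#' @param weights Numeric 9 x 20 matrix; columns must be named by the 20
#'   canonical residues (any order; stored in [aa_alphabet()] order).
#' @param allele HLA allele name (e.g. `"HLA-DRB1*01:01"`).
#' @return An object of class `pocket_profile`: the 9 x 20 weight matrix with
#'   an `allele` attribute.
#' @export
pocket_profile <- function(weights, allele) {
  .check_string(allele, "allele")
  weights <- as.matrix(weights)
  if (nrow(weights) != 9L) stop("pocket profile must have 9 positions",
                                call. = FALSE)
  if (is.null(colnames(weights)) ||
      !setequal(colnames(weights), aa_alphabet())) {
    stop("pocket profile columns must be the 20 canonical residues",
         call. = FALSE)
  }
  weights <- weights[, aa_alphabet(), drop = FALSE]
  storage.mode(weights) <- "double"
  rownames(weights) <- as.character(seq_len(9L))
  structure(weights, allele = allele, class = c("pocket_profile", "matrix"))
}

#' @export
print.pocket_profile <- function(x, ...) {
  cat(sprintf("<pocket_profile> allele %s, 9 positions x 20 residues\n",
              attr(x, "allele")))
  print(unclass(x)[, 1:6])
  cat("  ... (", 20L, "residue columns )\n")
  invisible(x)
}

#' Read a pocket-profile matrix file
#'
#' File dialect: a leading comment line `# allele=<name>`, a header row of
#' the 20 one-letter residues, then 9 tab-separated data rows (binding
#' positions 1-9).
#'
#' @param path Path to a matrix TSV.
#' @return A `pocket_profile`.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*allele\\s*=\\s*(\\S.*\\S|\\S)\\s*$",
                                 first))[[1L]]
  if (length(m) < 2L) {
    stop("matrix file must start with a '# allele=<name>' comment line: ",
         path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  pocket_profile(as.matrix(df), allele = m[2L])
}

#' Write a pocket-profile matrix file
#'
#' @param profile A `pocket_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pocket_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# allele=%s", attr(profile, "allele")), con)
  utils::write.table(unclass(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Map residue characters to matrix column indices; NA for non-canonical.
.residue_index <- function(chars) {
  match(chars, aa_alphabet())
}

#' Score a 9-mer core against a pocket profile
#'
#' The raw binding score is the sum over the nine binding positions of the
#' weight of the residue seated there; higher means stronger predicted
#' binding.
#'
#' @param profile A `pocket_profile`.
#' @param core 9-residue string over the canonical alphabet.
#' @return Numeric raw score.
#' @export
score_core <- function(profile, core) {
  stopifnot(inherits(profile, "pocket_profile"))
  .check_string(core, "core")
  if (nchar(core) != 9L) stop("core must be a 9-mer", call. = FALSE)
  idx <- .residue_index(.residues(core))
  if (anyNA(idx)) stop("core contains non-canonical residues: ", core,
                       call. = FALSE)
  sum(unclass(profile)[cbind(seq_len(9L), idx)])
}

# Vectorised core scoring: seqs is a character vector of 9-mers.
.score_cores <- function(profile, seqs) {
  w <- unclass(profile)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  ncol = 9L, byrow = TRUE)
  idx <- matrix(.residue_index(chars), ncol = 9L)
  if (anyNA(idx)) stop("non-canonical residues in core sequences",
                       call. = FALSE)
  out <- numeric(length(seqs))
  for (p in seq_len(9L)) out <- out + w[p, ][idx[, p]]
  unname(out)
}

#' Score a 15-mer window against a pocket profile
#'
#' A 15-mer seats one of seven possible 9-mer registers in the MHC-II groove;
#' the window's raw score is the best register's core score. Ties go to the
#' smallest offset, making scoring deterministic.
#'
#' @param profile A `pocket_profile`.
#' @param window 15-residue string (or a one-row window table from
#'   [window_peptides()]).
#' @return List with `raw` (best core score) and `best_core_offset`
#'   (0-based offset of the winning 9-mer frame, 0-6).
#' @export
score_window <- function(profile, window) {
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1L)
    window <- window$peptide
  }
  .check_string(window, "window")
  if (nchar(window) != 15L) stop("window must be a 15-mer", call. = FALSE)
  sc <- .score_window_batch(profile, window)
  list(raw = sc$raw[1L], best_core_offset = sc$offset[1L])
}

# Vectorised window scoring over the 7 frames of each 15-mer.
.score_window_batch <- function(profile, peptides) {
  n <- length(peptides)
  best <- rep(-Inf, n)
  offset <- rep(0L, n)
  for (off in 0:6) {
    sc <- .score_cores(profile, substr(peptides, off + 1L, off + 9L))
    improve <- sc > best            # strict: earliest offset wins ties
    best[improve] <- sc[improve]
    offset[improve] <- off
  }
  list(raw = best, offset = offset)
}
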