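# Redundancy reduction: pairwise identity and greedy incremental clustering
# at an identity cutoff (CD-HIT-style semantics).

# Substitution matrix for identity alignments: +1 canonical match, 0 mismatch.
# Ambiguity codes score 0 even against themselves (they never count as
# identical positions).
.identity_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- c(aa_alphabet(), AA_AMBIGUOUS)
      m <- matrix(0, nrow = length(letters), ncol = length(letters),
                  dimnames = list(letters, letters))
      diag(m)[aa_alphabet()] <- 1
      cache <<- m
    }
    cache
  }
})

.as_sequence <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single protein record", call. = FALSE)
    x <- x$sequence
  }
  .check_string(x, "sequence")
  toupper(x)
}

#' Pairwise sequence identity
#'
#' Fraction of identical positions in an optimal global alignment, divided by
#' the length of the shorter sequence (the denominator convention of CD-HIT).
#' The alignment scores match +1, mismatch 0, gap -0.5, with free end gaps;
#' ambiguity codes (X/B/Z/U) never count as identical positions.
#'
#' @param a,b Amino-acid sequences (strings, or single protein-record rows).
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIW") # 8/9
pairwise_identity <- function(a, b) {
  a <- .as_sequence(a)
  b <- .as_sequence(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "overlap",
    substitutionMatrix = .identity_submat(),
    gapOpening = 0, gapExtension = 0.5)
  # count identical canonical positions ourselves: nmatch() would also count
  # aligned ambiguity codes (X-X), which never score as identical here
  p <- .residues(as.character(Biostrings::pattern(aln)))
  s <- .residues(as.character(Biostrings::subject(aln)))
  sum(p == s & p %in% aa_alphabet()) / min(nchar(a), nchar(b))
}

#' Greedy incremental clustering at an identity cutoff
#'
#' Reduces a sequence set to non-redundant representatives: records are
#' processed longest-first (ties broken by id) and each joins the first
#' existing cluster whose representative it matches at or above the cutoff,
#' otherwise it founds a new cluster. This reproduces the greedy incremental
#' semantics of CD-HIT (without its word filter), so cluster representatives
#' are pairwise below the cutoff and members reach their representative at or
#' above it.
#'
#' @param records Protein record table.
#' @param cutoff Identity cutoff in `(0, 1]` (default 0.6).
#' @return A `data.frame` with columns `cluster` (integer, founding order),
#'   `representative_id`, `member_id`, `identity` (member vs representative;
#'   1 for the representative itself), with `cutoff` stored as an attribute.
#' @export
greedy_cluster <- function(records, cutoff = 0.6) {
  if (!nrow(records)) stop("records must be non-empty", call. = FALSE)
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]", call. = FALSE)
  ord <- order(-records$length, records$id, method = "radix")
  recs <- records[ord, , drop = FALSE]
  rep_idx <- integer(0)                     # row indices (into recs) of reps
  assignment <- integer(nrow(recs))
  identity <- numeric(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    placed <- FALSE
    for (k in seq_along(rep_idx)) {
      idy <- pairwise_identity(recs$sequence[i], recs$sequence[rep_idx[k]])
      if (idy >= cutoff) {
        assignment[i] <- k
        identity[i] <- idy
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- length(rep_idx)
      identity[i] <- 1
    }
  }
  out <- data.frame(cluster = assignment,
                    representative_id = recs$id[rep_idx[assignment]],
                    member_id = recs$id,
                    identity = identity,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -identity, out$member_id, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Cluster representatives
#'
#' @param clusters Result of [greedy_cluster()].
#' @return Character vector of representative ids, in founding order.
#' @export
cluster_representatives <- function(clusters) {
  unique(clusters$representative_id)
}

#' Write a cluster table to TSV
#'
#' @param clusters Result of [greedy_cluster()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  .write_tsv(clusters[c("representative_id", "member_id", "identity")], path)
}
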