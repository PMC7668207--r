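# Multi-criteria candidate selection against a reference enzyme.

# TRUE if candidate i is dominated by j on the three minimised criteria:
# j is <= i everywhere and strictly < somewhere.
.dominated <- function(crit) {
  n <- nrow(crit)
  dom <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      le <- crit[j, ] <= crit[i, ]
      lt <- crit[j, ] < crit[i, ]
      if (all(le) && any(lt)) { dom[i] <- TRUE; break }
    }
  }
  dom
}

#' Select low-immunogenicity candidates against a reference
#'
#' Candidates are compared on three "lower is better" criteria — epitope
#' density, allele coverage, and antigenicity probability — with no weights:
#' the Pareto front (candidates not dominated on all three jointly) is
#' selected, optionally restricted to one family. The reference protein is
#' never selected; it anchors the comparison.
#'
#' @param rows Screening table with columns `id`, `ed`, `allele_count`.
#' @param antigenicity `data.frame` with `id`, `probability` covering every
#'   row (see [read_antigenicity()]).
#' @param reference_id Reference protein id (present in `rows`).
#' @param family_labels Optional `data.frame` with `id`, `family`.
#' @param restrict_family Optional family label; when given, `selected` is
#'   the Pareto front restricted to that family.
#' @return An object of class `candidate_ranking`: list with `reference_id`,
#'   `table` (screening rows + `antigenicity`, `pareto`, `selected` columns,
#'   ordered by ascending ED, ties by allele count, antigenicity, then id),
#'   `ordered_ids`, `pareto_front`, `selected`.
#' @export
select_candidates <- function(rows, antigenicity, reference_id,
                              family_labels = NULL, restrict_family = NULL) {
  if (!reference_id %in% rows$id) {
    stop("reference id not found: ", reference_id, call. = FALSE)
  }
  idx <- match(rows$id, antigenicity$id)
  if (anyNA(idx)) {
    stop("missing antigenicity score for: ",
         paste(rows$id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tab <- rows
  tab$antigenicity <- antigenicity$probability[idx]
  if (!is.null(family_labels)) {
    tab$family <- family_labels$family[match(.strip_version(tab$id),
                                             .strip_version(family_labels$id))]
  }
  cand <- tab[tab$id != reference_id, , drop = FALSE]
  crit <- as.matrix(cand[c("ed", "allele_count", "antigenicity")])
  cand$pareto <- !.dominated(crit)
  cand$selected <- cand$pareto
  if (!is.null(restrict_family)) {
    if (is.null(family_labels)) {
      stop("restrict_family requires family_labels", call. = FALSE)
    }
    cand$selected <- cand$selected & !is.na(cand$family) &
      cand$family == restrict_family
  }
  ord <- order(cand$ed, cand$allele_count, cand$antigenicity, cand$id,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]
  ref <- tab[tab$id == reference_id, , drop = FALSE]
  ref$pareto <- FALSE
  ref$selected <- FALSE
  out_tab <- rbind(cand, ref)
  rownames(out_tab) <- NULL
  structure(list(reference_id = reference_id,
                 table = out_tab,
                 ordered_ids = cand$id,
                 pareto_front = cand$id[cand$pareto],
                 selected = cand$id[cand$selected]),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat(sprintf("<candidate_ranking> %d candidates vs reference %s\n",
              length(x$ordered_ids), x$reference_id))
  cat("Pareto front:", if (length(x$pareto_front))
    paste(x$pareto_front, collapse = ", ") else "(empty)", "\n")
  cat("Selected:    ", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a candidate ranking
#'
#' Writes the ranking table as TSV and the summary (reference, front,
#' selection) as JSON.
#'
#' @param ranking A `candidate_ranking`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_ranking <- function(ranking, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(ranking, "candidate_ranking"))
  written <- character(0)
  if (!is.null(tsv_path)) {
    .write_tsv(ranking$table, tsv_path)
    written <- c(written, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(reference_id = ranking$reference_id,
                              ordered_ids = ranking$ordered_ids,
                              pareto_front = ranking$pareto_front,
                              selected = ranking$selected),
                         json_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, json_path)
  }
  invisible(written)
}
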