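# Human-readable run report (markdown), mirroring the TSV outputs exactly.

.fmt_ed <- function(x) formatC(x, format = "f", digits = 6)

#' Render a screening report
#'
#' Produces a markdown summary of a completed run: stage counts, the
#' screening table with its ED extremes, the comparison to the reference,
#' per-protein epitope-density summaries, and the Pareto selection. Every
#' number is taken from the same tables the run wrote to disk.
#'
#' @param summary A `run_summary` from [run_screening()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(summary) {
  stopifnot(inherits(summary, "run_summary"))
  s <- summary$screening
  lines <- c("# Immunogenicity screening report", "",
             "## Stage counts", "")
  lines <- c(lines, vapply(names(summary$counts), function(n) {
    sprintf("- %s: %d", n, summary$counts[[n]])
  }, character(1L)), "")

  lines <- c(lines, "## Screening summary", "",
             "id\tepitopes\tmean_cpr\talleles\tlength\tED")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("%s\t%d\t%.4f\t%d\t%d\t%s",
                              s$id[i], s$epitope_count[i], s$mean_cpr[i],
                              s$allele_count[i], s$length[i],
                              .fmt_ed(s$ed[i])))
  }
  i_min <- which.min(s$ed)
  i_max <- which.max(s$ed)
  lines <- c(lines, "",
             sprintf("- Lowest ED: %s (ED = %s, %d alleles covered)",
                     s$id[i_min], .fmt_ed(s$ed[i_min]),
                     s$allele_count[i_min]),
             sprintf("- Highest ED: %s (ED = %s, %d alleles covered)",
                     s$id[i_max], .fmt_ed(s$ed[i_max]),
                     s$allele_count[i_max]), "")

  if (!is.null(summary$reference_comparison)) {
    ref <- summary$config$reference_id
    cmp <- summary$reference_comparison
    lines <- c(lines, "## Comparison to reference", "",
               sprintf("- Reference: %s (ED = %s)", ref,
                       .fmt_ed(s$ed[match(ref, s$id)])),
               if (length(cmp)) {
                 sprintf("- %d protein(s) with ED above the reference: %s",
                         length(cmp), paste(cmp, collapse = ", "))
               } else "- No protein exceeds the reference ED", "")
  }

  if (!is.null(summary$ranking)) {
    r <- summary$ranking
    lines <- c(lines, "## Candidate selection (Pareto on ED, allele coverage, antigenicity)",
               "",
               sprintf("- Pareto front: %s",
                       if (length(r$pareto_front))
                         paste(r$pareto_front, collapse = ", ")
                       else "(empty)"),
               sprintf("- Selected: %s",
                       if (length(r$selected))
                         paste(r$selected, collapse = ", ")
                       else "no candidates selected"), "")
  }

  if (!is.null(summary$density) && nrow(summary$density)) {
    lines <- c(lines, "## Epitope coverage along sequences", "")
    for (id in unique(summary$density$id)) {
      d <- summary$density[summary$density$id == id, , drop = FALSE]
      covered <- sum(d$count > 0L)
      lines <- c(lines, sprintf("- %s: %d/%d residues covered, max hits %d",
                                id, covered, nrow(d), max(d$count)))
    }
    lines <- c(lines, "")
  }

  if (length(summary$warnings)) {
    lines <- c(lines, "## Warnings", "",
               paste0("- ", summary$warnings), "")
  }
  lines
}
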