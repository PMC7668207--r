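# Orchestration: one reproducible run from FASTA + matrices + config to
# clusters, family labels, consensus records, screening rows, density maps,
# and a ranked candidate report.

#' Assemble a screening run configuration
#'
#' @param fasta Path to the input protein FASTA.
#' @param matrix_paths Character vector of pocket-profile matrix files (one
#'   per allele; see [read_pssm()]).
#' @param out_dir Output directory (created if absent).
#' @param reference_id Reference protein id for ED comparison and ranking
#'   (`NULL` to skip ranking).
#' @param antigenicity Optional antigenicity TSV path (required for ranking).
#' @param prediction_table Optional external prediction export TSV.
#' @param motif_file Motif definition TSV; default the packaged family
#'   signatures.
#' @param min_length,max_length Intake length bounds (default 316-428).
#' @param reject_ambiguous Reject X/B/Z/U at intake (default `TRUE`).
#' @param identity_cutoff Clustering identity cutoff (default 0.6).
#' @param binder_threshold,core_threshold CPR thresholds (defaults 2 and 1).
#' @param epitope_size ED denominator unit (default 9).
#' @param background_size Background peptides per allele (default 100000).
#' @param background_model `"uniform"` or `"swissprot"`.
#' @param restrict_family Optional family label restricting the selection.
#' @param seed Integer seed for background sampling.
#' @return An object of class `run_config` (validated list).
#' @export
run_config <- function(fasta, matrix_paths, out_dir,
                       reference_id = NULL, antigenicity = NULL,
                       prediction_table = NULL, motif_file = NULL,
                       min_length = 316L, max_length = 428L,
                       reject_ambiguous = TRUE, identity_cutoff = 0.6,
                       binder_threshold = 2, core_threshold = 1,
                       epitope_size = 9L, background_size = 100000L,
                       background_model = c("uniform", "swissprot"),
                       restrict_family = NULL, seed = 1L) {
  .check_string(fasta, "fasta")
  if (!length(matrix_paths)) stop("at least one matrix file is required",
                                  call. = FALSE)
  if (binder_threshold <= 0 || core_threshold <= 0 || identity_cutoff <= 0 ||
      identity_cutoff > 1) {
    stop("thresholds must be positive (identity cutoff in (0,1])",
         call. = FALSE)
  }
  structure(list(fasta = fasta, matrix_paths = matrix_paths,
                 out_dir = out_dir, reference_id = reference_id,
                 antigenicity = antigenicity,
                 prediction_table = prediction_table,
                 motif_file = motif_file,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 reject_ambiguous = isTRUE(reject_ambiguous),
                 identity_cutoff = identity_cutoff,
                 binder_threshold = binder_threshold,
                 core_threshold = core_threshold,
                 epitope_size = as.integer(epitope_size),
                 background_size = as.integer(background_size),
                 background_model = match.arg(background_model),
                 restrict_family = restrict_family,
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Executes intake -> clustering -> motif/family labelling -> epitope
#' prediction -> core extraction -> screening statistics -> ranking, writing
#' every intermediate table plus the resolved configuration (provenance) and
#' a human-readable report to the output directory. The run is a pure
#' function of its inputs and seed: replaying the stored configuration
#' reproduces every output byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, an object of class `run_summary`: stage counts,
#'   warnings, output paths, and the in-memory result tables.
#' @export
run_screening <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- function(f) file.path(config$out_dir, f)
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)

  jsonlite::write_json(unclass(config), paths("config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  # --- intake ---------------------------------------------------------------
  records <- .stage("intake", read_fasta(config$fasta))
  flt <- .stage("intake", filter_records(records, config$min_length,
                                         config$max_length,
                                         config$reject_ambiguous))
  if (!nrow(flt$kept)) {
    stop("stage 'intake' failed: no records pass the length/ambiguity filter",
         call. = FALSE)
  }
  .write_tsv(flt$kept[c("id", "length", "description")], paths("kept.tsv"))
  .write_tsv(if (nrow(flt$rejected))
               flt$rejected[c("id", "length", "reason")]
             else data.frame(id = character(0), length = integer(0),
                             reason = character(0)),
             paths("rejected.tsv"))

  # --- clustering -----------------------------------------------------------
  clusters <- .stage("cluster",
                     greedy_cluster(flt$kept, config$identity_cutoff))
  write_clusters(clusters, paths("clusters.tsv"))
  reps <- flt$kept[match(cluster_representatives(clusters), flt$kept$id), ,
                   drop = FALSE]
  rownames(reps) <- NULL

  # --- motif / family labelling --------------------------------------------
  motifs <- .stage("motifs", {
    if (is.null(config$motif_file)) asn_family_motifs()
    else read_motif_table(config$motif_file)
  })
  fams <- attr(motifs, "family")
  p710 <- motifs[fams == "PF00710.11"]
  p089 <- motifs[fams == "PF06089.11"]
  hit_tab <- .stage("motifs", scan_motifs(reps, motifs))
  .write_tsv(hit_tab, paths("motif_hits.tsv"))
  family <- vapply(seq_len(nrow(reps)), function(i) {
    assign_family(reps[i, , drop = FALSE], p710, p089)
  }, character(1L))
  family_tab <- data.frame(id = reps$id, family = family,
                           stringsAsFactors = FALSE)
  .write_tsv(family_tab, paths("families.tsv"))

  # --- epitope prediction ---------------------------------------------------
  profiles <- .stage("predict", {
    pr <- lapply(config$matrix_paths, read_pssm)
    names(pr) <- vapply(pr, attr, character(1L), "allele")
    pr
  })
  backgrounds <- .stage("predict",
    make_backgrounds(profiles, n = config$background_size,
                     frequencies = aa_frequencies(config$background_model),
                     seed = config$seed))
  extra <- if (!is.null(config$prediction_table)) {
    .stage("predict", read_prediction_table(config$prediction_table))
  } else NULL
  consensus <- .stage("predict",
                      predict_epitopes(reps, profiles, backgrounds, extra))
  .write_tsv(consensus[c("protein_id", "start", "allele", "cpr",
                         "n_methods")], paths("consensus.tsv"))

  # --- core extraction ------------------------------------------------------
  cores <- .stage("extract",
                  extract_cores(consensus, reps, profiles, backgrounds,
                                config$binder_threshold,
                                config$core_threshold))
  .write_tsv(cores, paths("cores.tsv"))

  # --- screening statistics -------------------------------------------------
  screening <- .stage("screen",
                      build_screening_table(reps, cores, config$epitope_size))
  write_screening_table(screening, paths("screening.tsv"))
  density <- .stage("screen", {
    do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
      counts <- density_map(cores[cores$protein_id == reps$id[i], ,
                                  drop = FALSE], reps$length[i])
      data.frame(id = reps$id[i], position = seq_along(counts),
                 count = counts, stringsAsFactors = FALSE)
    }))
  })
  .write_tsv(density, paths("density.tsv"))

  # --- ranking --------------------------------------------------------------
  ranking <- NULL
  reference_comparison <- NULL
  if (!is.null(config$reference_id)) {
    if (!config$reference_id %in% screening$id) {
      stop("stage 'rank' failed: reference id '", config$reference_id,
           "' is not among the screened representatives", call. = FALSE)
    }
    reference_comparison <- .stage("rank",
      compare_to_reference(screening, config$reference_id))
    if (!is.null(config$antigenicity)) {
      anti <- .stage("rank", read_antigenicity(config$antigenicity))
      ranking <- .stage("rank",
        select_candidates(screening, anti, config$reference_id,
                          family_labels = family_tab,
                          restrict_family = config$restrict_family))
      write_ranking(ranking, paths("ranking.tsv"), paths("ranking.json"))
    } else {
      note("no antigenicity table supplied; Pareto ranking skipped")
    }
  }

  summary <- structure(list(
    config = config,
    counts = list(records = nrow(records), kept = nrow(flt$kept),
                  rejected = nrow(flt$rejected),
                  clusters = length(unique(clusters$cluster)),
                  representatives = nrow(reps),
                  windows = sum(pmax(reps$length - 14L, 0L)),
                  consensus_records = nrow(consensus),
                  cores = nrow(cores),
                  screened = nrow(screening)),
    family = family_tab,
    screening = screening,
    cores = cores,
    density = density,
    reference_comparison = reference_comparison,
    ranking = ranking,
    warnings = warnings,
    out_dir = config$out_dir), class = "run_summary")
  writeLines(render_report(summary), paths("report.md"))
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  for (n in names(x$counts)) cat(sprintf("  %-18s %d\n", n, x$counts[[n]]))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}
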