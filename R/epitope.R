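# Epitope prediction: 15-mer windowing, percentile calibration against random
# backgrounds, consensus percentile ranks (CPR), and 9-mer core extraction.

#' Tile a protein into overlapping peptide windows
#'
#' @param record Single protein record row (or record table; all rows tiled).
#' @param k Window length in residues (default 15, the MHC-II scanning unit).
#' @return A `data.frame` with columns `protein_id`, `start` (1-based),
#'   `peptide`. A protein shorter than `k` contributes no windows (with a
#'   warning).
#' @export
window_peptides <- function(record, k = 15L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  out <- lapply(seq_len(nrow(record)), function(r) {
    len <- record$length[r]
    if (len < k) {
      warning(sprintf("protein '%s' (length %d) is shorter than the window (%d); no windows generated",
                      record$id[r], len, k), call. = FALSE)
      return(NULL)
    }
    starts <- seq_len(len - k + 1L)
    data.frame(protein_id = record$id[r], start = starts,
               peptide = substring(record$sequence[r], starts, starts + k - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), start = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build a random-peptide score background
#'
#' Samples `n` random peptides residue-wise from a stated frequency model,
#' scores them under the pocket profile, and stores the sorted raw scores.
#' Percentile ranks of query peptides are computed against this set, standing
#' in for the large random-peptide backgrounds MHC-II prediction services
#' calibrate against.
#'
#' @param profile A `pocket_profile`.
#' @param n Background size (default 100000).
#' @param k Peptide length: 15 (windows, scored as best 9-mer frame) or 9
#'   (cores, scored directly).
#' @param frequencies Named residue frequency vector over [aa_alphabet()]
#'   (see [aa_frequencies()]); default uniform.
#' @param seed Integer seed; the background is a pure function of
#'   (profile, n, k, frequencies, seed).
#' @return An object of class `background_set`: list with `allele`, `method`,
#'   `k`, `n`, and sorted `scores`.
#' @export
make_background <- function(profile, n = 100000L, k = 15L,
                            frequencies = aa_frequencies("uniform"),
                            seed = 1L) {
  stopifnot(inherits(profile, "pocket_profile"))
  n <- as.integer(n)
  if (n < 1L) stop("background size must be >= 1", call. = FALSE)
  if (!k %in% c(9L, 15L)) stop("k must be 9 or 15", call. = FALSE)
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  frequencies <- frequencies[aa_alphabet()]
  peptides <- .with_seed(seed, {
    chars <- matrix(sample(aa_alphabet(), n * k, replace = TRUE,
                           prob = frequencies), ncol = k)
    apply(chars, 1L, paste, collapse = "")
  })
  scores <- if (k == 9L) .score_cores(profile, peptides)
            else .score_window_batch(profile, peptides)$raw
  structure(list(allele = attr(profile, "allele"), method = "pocket_profile",
                 k = as.integer(k), n = n, scores = sort(scores)),
            class = "background_set")
}

# Evaluate an expression under a private seed, leaving the caller's RNG
# stream untouched.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  prev <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", prev, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Backgrounds for an allele panel
#'
#' Convenience wrapper building, for every allele matrix, both the 15-mer
#' window background and the 9-mer core background used by
#' [predict_epitopes()] and [extract_cores()].
#'
#' @param profiles Named list of `pocket_profile`s (names = alleles).
#' @param n Background size per background.
#' @param frequencies Residue frequencies (see [aa_frequencies()]).
#' @param seed Integer seed; per-allele seeds are derived deterministically.
#' @return Named list (by allele) of lists with elements `window` and `core`,
#'   each a `background_set`.
#' @export
make_backgrounds <- function(profiles, n = 100000L,
                             frequencies = aa_frequencies("uniform"),
                             seed = 1L) {
  stopifnot(length(profiles) > 0L)
  out <- vector("list", length(profiles))
  names(out) <- names(profiles)
  for (i in seq_along(profiles)) {
    s <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    out[[i]] <- list(window = make_background(profiles[[i]], n = n, k = 15L,
                                              frequencies = frequencies,
                                              seed = s),
                     core = make_background(profiles[[i]], n = n, k = 9L,
                                            frequencies = frequencies,
                                            seed = s + 1L))
  }
  out
}

#' Percentile rank of a raw score against a background
#'
#' The percentile rank is the percentage of background peptides scoring
#' strictly better than the query: 0 for a score above the whole background,
#' 100 for one below it. Lower percentile = stronger predicted binder. Ties
#' with background scores do not penalise the query.
#'
#' @param raw Numeric vector of raw scores.
#' @param background A `background_set`.
#' @return Numeric vector of percentiles in `[0, 100]`.
#' @export
calibrate_percentile <- function(raw, background) {
  if (!inherits(background, "background_set") || background$n < 1L) {
    stop("background must be a non-empty background_set", call. = FALSE)
  }
  n_le <- findInterval(raw, background$scores)   # scores <= raw
  100 * (background$n - n_le) / background$n
}

#' Consensus percentile rank
#'
#' The median of the per-method percentile ranks for one peptide-allele pair
#' (mean of the two central order statistics for even method counts).
#'
#' @param percentiles Numeric vector of per-method percentiles (length >= 1).
#' @return The consensus percentile rank.
#' @export
consensus_rank <- function(percentiles) {
  if (!length(percentiles) || anyNA(percentiles)) {
    stop("at least one method percentile is required", call. = FALSE)
  }
  stats::median(percentiles)
}

#' Predict per-window consensus percentile ranks
#'
#' Scores every 15-mer window of every protein under each allele's pocket
#' profile, calibrates percentile ranks against the allele's window
#' background, and combines them with any externally supplied method
#' percentiles into a consensus percentile rank (CPR, the median across
#' methods). With only the pocket-profile method configured the CPR equals
#' its percentile.
#'
#' @param records Protein record table.
#' @param profiles Named list of `pocket_profile`s (names = alleles).
#' @param backgrounds Result of [make_backgrounds()] for the same alleles.
#' @param extra_methods Optional prediction table from
#'   [read_prediction_table()]: external per-method percentiles joined by
#'   (protein_id, start, allele) and entered into the median.
#' @return A `data.frame` with one row per (window, allele): `protein_id`,
#'   `start`, `peptide`, `allele`, `pocket_raw`, `best_core_offset`,
#'   `pocket_percentile`, `cpr`, `n_methods`.
#' @export
predict_epitopes <- function(records, profiles, backgrounds,
                             extra_methods = NULL) {
  if (!length(profiles)) stop("at least one allele profile required",
                              call. = FALSE)
  missing_bg <- setdiff(names(profiles), names(backgrounds))
  if (length(missing_bg)) {
    stop("no background configured for allele(s): ",
         paste(missing_bg, collapse = ", "), call. = FALSE)
  }
  windows <- window_peptides(records, k = 15L)
  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    allele <- names(profiles)[i]
    sc <- .score_window_batch(profiles[[i]], windows$peptide)
    pct <- calibrate_percentile(sc$raw, backgrounds[[allele]]$window)
    df <- data.frame(windows, allele = allele, pocket_raw = sc$raw,
                     best_core_offset = sc$offset, pocket_percentile = pct,
                     cpr = pct, n_methods = 1L, stringsAsFactors = FALSE)
    out[[i]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(extra_methods) && nrow(extra_methods)) {
    key <- paste(out$protein_id, out$start, out$allele, sep = "\r")
    ekey <- paste(extra_methods$protein_id, extra_methods$start,
                  extra_methods$allele, sep = "\r")
    extra_split <- split(extra_methods$percentile, ekey)
    idx <- match(key, names(extra_split))
    has_extra <- which(!is.na(idx))
    for (j in has_extra) {
      per_method <- c(out$pocket_percentile[j], extra_split[[idx[j]]])
      out$cpr[j] <- consensus_rank(per_method)
      out$n_methods[j] <- length(per_method)
    }
    uncovered <- setdiff(names(extra_split), key)
    if (length(uncovered)) {
      message(sprintf("%d external prediction row group(s) matched no scored window and were ignored",
                      length(uncovered)))
    }
  }
  out
}

#' Extract high-affinity 9-mer cores
#'
#' From windows whose CPR is below the binder threshold, takes each window's
#' best 9-mer register per allele, scores that core directly under the pocket
#' profile, calibrates it against the allele's 9-mer background, and retains
#' cores whose own percentile is below the core threshold. Cores reached from
#' several overlapping windows are reported once per (protein, allele, start),
#' countering the over-counting that overlapping 15-mers would otherwise
#' cause.
#'
#' @param consensus Output of [predict_epitopes()].
#' @param records Protein record table (to slice core sequences).
#' @param profiles,backgrounds As in [predict_epitopes()].
#' @param binder_threshold CPR below which a window counts as a high-affinity
#'   binder (default 2).
#' @param core_threshold Core-percentile cutoff for retaining a 9-mer core
#'   (default 1).
#' @return A `data.frame` with columns `protein_id`, `allele`, `core`,
#'   `start` (1-based position of the core in the protein), `core_cpr`,
#'   `n_source_windows`, `source_windows` (comma-separated window starts).
#' @export
extract_cores <- function(consensus, records, profiles, backgrounds,
                          binder_threshold = 2, core_threshold = 1) {
  if (binder_threshold <= 0 || core_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  empty <- data.frame(protein_id = character(0), allele = character(0),
                      core = character(0), start = integer(0),
                      core_cpr = numeric(0), n_source_windows = integer(0),
                      source_windows = character(0), stringsAsFactors = FALSE)
  hits <- consensus[consensus$cpr < binder_threshold, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  seq_by_id <- stats::setNames(records$sequence, records$id)
  hits$core_start <- hits$start + hits$best_core_offset
  hits$core <- substr(seq_by_id[hits$protein_id], hits$core_start,
                      hits$core_start + 8L)
  # score each distinct (allele, core) once
  out <- lapply(split(hits, hits$allele), function(h) {
    allele <- h$allele[1L]
    cores <- unique(h$core)
    sc <- .score_cores(profiles[[allele]], cores)
    pct <- calibrate_percentile(sc, backgrounds[[allele]]$core)
    h$core_cpr <- pct[match(h$core, cores)]
    h[h$core_cpr < core_threshold, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (!nrow(out)) return(empty)
  key <- paste(out$protein_id, out$allele, out$core_start, sep = "\r")
  agg <- lapply(split(out, key), function(g) {
    data.frame(protein_id = g$protein_id[1L], allele = g$allele[1L],
               core = g$core[1L], start = g$core_start[1L],
               core_cpr = g$core_cpr[1L],
               n_source_windows = nrow(g),
               source_windows = paste(sort(g$start), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$protein_id, res$allele, res$start, method = "radix"), ]
  rownames(res) <- NULL
  res
}

#' Read an external prediction export
#'
#' Ingests peptide x allele x method percentile tables exported from an
#' external MHC-II prediction service, so their percentiles can enter the
#' consensus median alongside the in-package pocket-profile method.
#'
#' @param path TSV with columns `protein_id`, `start`, `peptide`, `allele`,
#'   `method`, `percentile`.
#' @return Validated `data.frame` with those columns.
#' @export
read_prediction_table <- function(path) {
  df <- .read_tsv(path, required = c("protein_id", "start", "peptide",
                                     "allele", "method", "percentile"))
  if (!nrow(df)) return(df)
  df$start <- as.integer(df$start)
  df$percentile <- as.numeric(df$percentile)
  bad <- which(is.na(df$percentile) | df$percentile < 0 | df$percentile > 100)
  if (length(bad)) {
    stop(sprintf("prediction table %s row %d: percentile out of [0,100]",
                 path, bad[1L]), call. = FALSE)
  }
  badlen <- which(nchar(df$peptide) != 15L)
  if (length(badlen)) {
    stop(sprintf("prediction table %s row %d: peptide is not a 15-mer",
                 path, badlen[1L]), call. = FALSE)
  }
  badstart <- which(is.na(df$start) | df$start < 1L)
  if (length(badstart)) {
    stop(sprintf("prediction table %s row %d: invalid start",
                 path, badstart[1L]), call. = FALSE)
  }
  df
}
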