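# Independent oracles and tiny fixture builders used across the suite.

# Random amino-acid sequence (uses the ambient RNG; tests set their seed).
rand_seq <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force ends-free global alignment oracle (match +1, mismatch 0,
# internal gap -0.5, free end gaps). Returns the optimal score and the
# range of match counts attainable by score-optimal alignments, via a
# lexicographic DP on combined = 100 * (2*score) +/- matches.
align_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  m <- length(A)
  n <- length(B)
  run <- function(sign) {
    H <- matrix(-1e9, m + 1L, n + 1L)
    H[1L, ] <- 0
    H[, 1L] <- 0
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        hit <- A[i] == B[j]
        diag <- H[i, j] + (if (hit) 200 + sign else 0)
        up <- H[i, j + 1L] - 100       # consume A[i] against a gap
        left <- H[i + 1L, j] - 100     # consume B[j] against a gap
        H[i + 1L, j + 1L] <- max(diag, up, left)
      }
    }
    max(H[m + 1L, ], H[, n + 1L])      # free trailing gaps
  }
  dec <- function(combined, sign) {
    if (sign > 0) {
      list(score2 = combined %/% 100, matches = combined %% 100)
    } else {
      r <- combined %% 100
      mm <- if (r == 0) 0 else 100 - r
      list(score2 = (combined + mm) %/% 100, matches = mm)
    }
  }
  hi <- dec(run(+1), +1)
  lo <- dec(run(-1), -1)
  stopifnot(hi$score2 == lo$score2)
  list(score = hi$score2 / 2, max_matches = hi$matches,
       min_matches = lo$matches)
}

# Regular-expression motif-scan oracle: overlapping occurrences via a
# zero-width lookahead.
regex_scan_oracle <- function(seq, notation) {
  re <- gsub("x", ".", gsub("x\\((\\d+)\\)", ".{\\1}", notation))
  m <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Exhaustive Pareto-dominance oracle over minimised criteria rows.
pareto_oracle <- function(crit) {
  n <- nrow(crit)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n)[-i], function(j) {
      all(crit[j, ] <= crit[i, ]) && any(crit[j, ] < crit[i, ])
    }, logical(1L)))
  }, logical(1L))
}

# Brute-force strictly-greater percentile counting.
percentile_oracle <- function(raw, scores) {
  100 * sum(scores > raw) / length(scores)
}

# Write protein records to a temporary FASTA file; returns the path.
write_fasta_tmp <- function(records, width = 60L) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i],
                      if (nzchar(records$description[i]))
                        paste0(" ", records$description[i]) else ""), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  path
}

# Tiny deterministic allele panel for epitope tests: profiles + backgrounds
# favouring the given cores, one allele per core.
toy_panel <- function(cores, alleles = sprintf("HLA-DRB1*%02d:01",
                                               seq_along(cores)),
                      contrast = 12, bg_n = 2000L, seed = 42L) {
  profiles <- mapply(function(core, allele, i) {
    generate_pssm(allele, core, contrast = contrast, seed = seed + i)
  }, cores, alleles, seq_along(cores), SIMPLIFY = FALSE)
  names(profiles) <- alleles
  list(profiles = profiles,
       backgrounds = make_backgrounds(profiles, n = bg_n, seed = seed))
}
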