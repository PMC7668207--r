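zero_profile <- function(allele = "HLA-DRB1*01:01") {
  pocket_profile(matrix(0, 9, 20, dimnames = list(NULL, aa_alphabet())),
                 allele)
}

test_that("window_peptides tiles L - k + 1 windows with exact slices", {
  set.seed(1)
  rec <- protein_records("P1", rand_seq(17))
  w <- window_peptides(rec)
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, 1:3)
  expect_equal(w$peptide[2], substr(rec$sequence, 2, 16))

  exact <- protein_records("P2", rand_seq(15))
  w2 <- window_peptides(exact)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$peptide, exact$sequence)

  long <- protein_records("P3", rand_seq(332))
  expect_equal(nrow(window_peptides(long)), 318L)

  short <- protein_records("P4", rand_seq(10))
  expect_warning(w3 <- window_peptides(short), "shorter than the window")
  expect_equal(nrow(w3), 0L)
})

test_that("score_core sums positional weights", {
  expect_equal(score_core(zero_profile(), "ACDEFGHIK"), 0)
  m <- matrix(0, 9, 20, dimnames = list(NULL, aa_alphabet()))
  m[, "A"] <- 1
  expect_equal(score_core(pocket_profile(m, "X"), "AAAAAAAAA"), 9)
  # unit weights at positions 1, 4, 6, 9 matching the core's residues
  core <- "ACDEFGHIK"
  m2 <- matrix(0, 9, 20, dimnames = list(NULL, aa_alphabet()))
  for (p in c(1, 4, 6, 9)) m2[p, substr(core, p, p)] <- 1
  expect_equal(score_core(pocket_profile(m2, "X"), core), 4)
  expect_error(score_core(zero_profile(), "ACDEFGHI"), "9-mer")
  expect_error(score_core(zero_profile(), "ACDEFGHIX"), "non-canonical")
})

test_that("score_window maximises over the seven frames, ties to smallest offset", {
  set.seed(2)
  window <- rand_seq(15)
  planted <- substr(window, 4, 12)                     # offset 3
  m <- matrix(0, 9, 20, dimnames = list(NULL, aa_alphabet()))
  for (p in 1:9) m[p, substr(planted, p, p)] <- m[p, substr(planted, p, p)] + 1
  sw <- score_window(pocket_profile(m, "X"), window)
  # oracle: explicit frame enumeration
  frames <- vapply(0:6, function(off)
    score_core(pocket_profile(m, "X"), substr(window, off + 1, off + 9)),
    numeric(1))
  expect_equal(sw$raw, max(frames))
  expect_equal(sw$best_core_offset, which.max(frames) - 1L)
  expect_equal(sw$best_core_offset, 3L)

  z <- score_window(zero_profile(), window)
  expect_equal(z$raw, 0)
  expect_equal(z$best_core_offset, 0L)                 # tie rule

  # a 12-residue C run: frames at offsets 2..5 all score 9 -> earliest wins
  seq15 <- "AACCCCCCCCCCCCA"
  mC <- matrix(0, 9, 20, dimnames = list(NULL, aa_alphabet()))
  mC[, "C"] <- 1
  swc <- score_window(pocket_profile(mC, "X"), seq15)
  expect_equal(swc$best_core_offset, 2L)
})

test_that("score_window agrees with frame enumeration on random proteins", {
  set.seed(3)
  prof <- generate_pssm("HLA-DRB1*01:01", rand_seq(9), contrast = 5, seed = 9)
  rec <- protein_records("P", rand_seq(60))
  w <- window_peptides(rec)
  for (i in seq_len(nrow(w))) {
    sw <- score_window(prof, w$peptide[i])
    frames <- vapply(0:6, function(off)
      score_core(prof, substr(w$peptide[i], off + 1, off + 9)), numeric(1))
    expect_equal(sw$raw, max(frames))
    expect_equal(sw$best_core_offset,
                 min(which(frames == max(frames))) - 1L)
  }
})

test_that("calibrate_percentile counts strictly-greater background scores", {
  bg <- structure(list(allele = "A", method = "pocket_profile", k = 9L,
                       n = 9L, scores = sort(as.numeric(1:9))),
                  class = "background_set")
  expect_equal(calibrate_percentile(10, bg), 0)
  expect_equal(calibrate_percentile(5, bg), 100 * 4 / 9)
  expect_equal(calibrate_percentile(0, bg), 100)
  expect_equal(calibrate_percentile(5.5, bg), 100 * 4 / 9)  # ties don't penalise
  expect_error(calibrate_percentile(1, list(scores = numeric(0))),
               "background")
})

test_that("calibrate_percentile equals brute-force counting and is monotone", {
  set.seed(4)
  scores <- rnorm(5000)
  bg <- structure(list(allele = "A", method = "pocket_profile", k = 9L,
                       n = length(scores), scores = sort(scores)),
                  class = "background_set")
  queries <- c(rnorm(200), sample(scores, 50), min(scores) - 1,
               max(scores) + 1)
  got <- calibrate_percentile(queries, bg)
  want <- vapply(queries, percentile_oracle, numeric(1), scores = scores)
  expect_equal(got, want)
  expect_equal(calibrate_percentile(max(scores) + 1, bg), 0)
  expect_equal(calibrate_percentile(min(scores) - 1, bg), 100)
  ord <- order(queries)
  expect_true(all(diff(got[ord]) <= 1e-12))
})

test_that("consensus_rank is the median: permutation-invariant, bounded, fixed point", {
  expect_equal(consensus_rank(c(0.5, 1.5, 3.5)), 1.5)
  expect_equal(consensus_rank(c(1, 2, 3, 4)), 2.5)
  expect_equal(consensus_rank(0.8), 0.8)
  expect_error(consensus_rank(numeric(0)), "at least one")
  set.seed(5)
  for (rep in 1:50) {
    x <- runif(sample(1:7, 1), 0, 100)
    expect_equal(consensus_rank(x[sample.int(length(x))]), consensus_rank(x))
    expect_gte(consensus_rank(x), min(x))
    expect_lte(consensus_rank(x), max(x))
  }
})

test_that("predict_epitopes yields one consensus record per window-allele pair", {
  set.seed(6)
  panel <- toy_panel(c("ACDEFGHIK", "MNPQRSTVW"))
  rec <- protein_records("P1", rand_seq(30))
  cons <- predict_epitopes(rec, panel$profiles, panel$backgrounds)
  expect_equal(nrow(cons), 16L * 2L)
  expect_equal(cons$cpr, cons$pocket_percentile)    # single-method median
  expect_true(all(cons$n_methods == 1L))
  expect_error(predict_epitopes(rec, panel$profiles,
                                panel$backgrounds[1]), "background")
})

test_that("a planted strong binder lowers the minimum CPR for its allele only", {
  set.seed(7)
  core <- "ACDEFGHIK"
  panel <- toy_panel(c(core, "MNPQRSTVW"))
  seqs <- rand_seq(60)
  substr(seqs, 20, 28) <- core
  rec <- protein_records("P1", seqs)
  cons <- predict_epitopes(rec, panel$profiles, panel$backgrounds)
  a <- names(panel$profiles)[1]
  b <- names(panel$profiles)[2]
  expect_lt(min(cons$cpr[cons$allele == a]), min(cons$cpr[cons$allele == b]))
  expect_equal(min(cons$cpr[cons$allele == a]), 0)
})

test_that("external method percentiles enter the consensus median", {
  set.seed(8)
  panel <- toy_panel("ACDEFGHIK")
  rec <- protein_records("P1", rand_seq(20))
  cons0 <- predict_epitopes(rec, panel$profiles, panel$backgrounds)
  allele <- names(panel$profiles)[1]
  extra <- data.frame(protein_id = "P1", start = c(1L, 1L), peptide =
                        substr(rec$sequence, 1, 15),
                      allele = allele, method = c("nn_align", "smm_align"),
                      percentile = c(10, 20), stringsAsFactors = FALSE)
  cons <- predict_epitopes(rec, panel$profiles, panel$backgrounds, extra)
  i <- which(cons$start == 1L)
  expect_equal(cons$n_methods[i], 3L)
  expect_equal(cons$cpr[i],
               median(c(cons0$pocket_percentile[cons0$start == 1L], 10, 20)))
  # other windows untouched
  expect_equal(cons$cpr[-i], cons0$cpr[-i])
})

test_that("extract_cores deduplicates overlapping windows into one core", {
  set.seed(9)
  core <- "ACDEFGHIK"
  panel <- toy_panel(core, bg_n = 4000)
  seqs <- rand_seq(40)
  substr(seqs, 16, 24) <- core
  rec <- protein_records("P1", seqs)
  cons <- predict_epitopes(rec, panel$profiles, panel$backgrounds)
  cores <- extract_cores(cons, rec, panel$profiles, panel$backgrounds)
  planted <- cores[cores$start == 16L & cores$core == core, ]
  expect_equal(nrow(planted), 1L)
  # the planted core is reachable from up to 7 overlapping qualifying windows
  expect_gte(planted$n_source_windows, 4L)
  expect_lt(planted$core_cpr, 1)
  # slices re-extract exactly
  expect_equal(substr(seqs, planted$start, planted$start + 8), planted$core)
})

test_that("extract_cores respects thresholds and is monotone in them", {
  set.seed(10)
  core <- "ACDEFGHIK"
  panel <- toy_panel(core, bg_n = 4000)
  seqs <- rand_seq(50)
  substr(seqs, 21, 29) <- core
  rec <- protein_records("P1", seqs)
  cons <- predict_epitopes(rec, panel$profiles, panel$backgrounds)
  # nothing below an absurdly small binder threshold is impossible for the
  # planted core (cpr 0), so instead: no window below threshold -> empty
  none <- extract_cores(cons[cons$cpr >= 2, ], rec, panel$profiles,
                        panel$backgrounds)
  expect_equal(nrow(none), 0L)
  n_prev <- -1L
  for (bt in c(0.5, 1, 2, 5)) {
    n <- nrow(extract_cores(cons, rec, panel$profiles, panel$backgrounds,
                            binder_threshold = bt))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  n_prev <- -1L
  for (ct in c(0.2, 1, 3, 10)) {
    n <- nrow(extract_cores(cons, rec, panel$profiles, panel$backgrounds,
                            core_threshold = ct))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  expect_error(extract_cores(cons, rec, panel$profiles, panel$backgrounds,
                             binder_threshold = 0), "positive")
})

test_that("read_prediction_table validates rows with their index", {
  ok <- tempfile(fileext = ".tsv")
  df <- data.frame(protein_id = "P1", start = 1:3,
                   peptide = strrep("A", 15), allele = "X",
                   method = "nn_align", percentile = c(1, 50, 99.9))
  write.table(df, ok, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_prediction_table(ok)), 3L)

  bad <- tempfile(fileext = ".tsv")
  df$percentile[2] <- 101
  write.table(df, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_prediction_table(bad), "row 2")

  badlen <- tempfile(fileext = ".tsv")
  df$percentile[2] <- 50
  df$peptide <- strrep("A", 14)
  write.table(df, badlen, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_prediction_table(badlen), "15-mer")

  missing_col <- tempfile(fileext = ".tsv")
  write.table(df[, -6], missing_col, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_prediction_table(missing_col), "percentile")
})

test_that("backgrounds are deterministic per seed and leave the RNG stream alone", {
  prof <- zero_profile()
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  b1 <- make_background(prof, n = 500, seed = 99)
  after <- runif(1)
  expect_equal(before, after)
  b2 <- make_background(prof, n = 500, seed = 99)
  expect_identical(b1, b2)
})

test_that("chance discoveries under uninformative matrices stay below one percent of windows", {
  # matrices favour cores absent from the proteome, so every retained core is
  # a calibration-tail false positive
  alleles <- hla_panel()[1:2]
  profiles <- list(generate_pssm(alleles[1], "AAAAAAAAA", 10, seed = 61),
                   generate_pssm(alleles[2], "CCCCCCCCC", 10, seed = 62))
  names(profiles) <- alleles
  bgs <- make_backgrounds(profiles, n = 10000, seed = 63)
  pro <- generate_proteome(synthetic_spec(6, c(300, 430), alleles = alleles,
                                          seed = 64))
  cons <- predict_epitopes(pro$records, profiles, bgs)
  cores <- extract_cores(cons, pro$records, profiles, bgs)
  expect_lte(nrow(cores) / nrow(cons), 0.01)
})
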