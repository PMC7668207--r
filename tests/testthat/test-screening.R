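core_row <- function(protein_id, allele, core, start, core_cpr = 0.5) {
  data.frame(protein_id = protein_id, allele = allele, core = core,
             start = start, core_cpr = core_cpr, n_source_windows = 1L,
             source_windows = as.character(start), stringsAsFactors = FALSE)
}

test_that("epitope_density evaluates the screening formula", {
  expect_equal(epitope_density(0, 0.5, 350), 0)
  expect_equal(epitope_density(1, 1.0, 109), 1 / 101)
  expect_equal(epitope_density(5, 0.5, 350), 5 * 1.5 / 342)
  expect_equal(epitope_density(3, 0.5, 332), 3 * 1.5 / 324)
  # epitope_size is configurable
  expect_equal(epitope_density(2, 1, 100, epitope_size = 15), 2 / 86)
  expect_error(epitope_density(1, 0.5, 5), "length")
  expect_error(epitope_density(1, 2.0, 100), "mean_cpr")
  expect_error(epitope_density(-1, 0.5, 100), "epitope_count")
})

test_that("epitope_density algebraic properties hold over small-integer sweeps", {
  for (len in c(50L, 109L, 332L, 421L)) {
    for (n in 0:6) {
      for (cpr in c(0, 0.25, 0.5, 1, 1.5, 1.99)) {
        ed <- epitope_density(n, cpr, len)
        expect_gte(ed, 0)
        expect_equal(ed == 0, n == 0)
        # exact rational form matches floating evaluation
        expect_equal(ed, n * (2 - cpr) / (len - 8), tolerance = 1e-12)
        # linear in count
        expect_equal(epitope_density(2 * n, cpr, len), 2 * ed,
                     tolerance = 1e-12)
      }
      if (n > 0) {
        # strictly decreasing in mean CPR and in length
        cprs <- seq(0, 1.9, by = 0.1)
        eds <- vapply(cprs, function(x) epitope_density(n, x, len),
                      numeric(1))
        expect_true(all(diff(eds) < 0))
        expect_lt(epitope_density(n, 0.5, len + 10),
                  epitope_density(n, 0.5, len))
      }
    }
  }
})

test_that("allele_coverage counts distinct alleles", {
  cores <- rbind(core_row("P", "A", "ACDEFGHIK", 1),
                 core_row("P", "B", "ACDEFGHIK", 1),
                 core_row("P", "A", "CDEFGHIKL", 12))
  expect_equal(allele_coverage(cores), 2L)
  expect_equal(allele_coverage(cores[0, ]), 0L)
  eight <- do.call(rbind, lapply(seq_along(hla_panel()), function(i)
    core_row("P", hla_panel()[i], "ACDEFGHIK", i * 10)))
  expect_equal(allele_coverage(eight), 8L)
  mixed <- rbind(core_row("P", "A", "ACDEFGHIK", 1),
                 core_row("Q", "A", "ACDEFGHIK", 1))
  expect_error(allele_coverage(mixed), "single protein")
})

test_that("density_map counts per-residue coverage and conserves mass", {
  one <- core_row("P", "A", "ACDEFGHIK", 10)
  dm <- density_map(one, 30)
  expect_equal(sum(dm), 9L)
  expect_equal(dm[10:18], rep(1L, 9))
  expect_equal(dm[c(1:9, 19:30)], rep(0L, 21))

  two <- rbind(one, core_row("P", "B", "ACDEFGHIK", 10))
  expect_equal(density_map(two, 30)[10:18], rep(2L, 9))

  expect_equal(density_map(one[0, ], 30), integer(30))
  expect_error(density_map(core_row("P", "A", "ACDEFGHIK", 25), 30),
               "outside")

  set.seed(11)
  for (rep in 1:20) {
    len <- sample(40:80, 1)
    k <- sample(0:6, 1)
    cores <- if (k == 0) one[0, ] else do.call(rbind, lapply(seq_len(k),
      function(i) core_row("P", sample(LETTERS[1:3], 1), strrep("A", 9),
                           sample(len - 8, 1))))
    expect_equal(sum(density_map(cores, len)), 9L * k)
  }
})

test_that("build_screening_row pools epitopes across alleles and applies the formula", {
  set.seed(12)
  prot <- protein_records("P", rand_seq(332))
  expect_equal(build_screening_row(prot, core_row("P", "A", "X", 1)[0, ])$ed, 0)

  three <- rbind(core_row("P", "A", "AAAAAAAAA", 10, 0.5),
                 core_row("P", "B", "CCCCCCCCC", 30, 0.5),
                 core_row("P", "A", "DDDDDDDDD", 50, 0.5))
  row <- build_screening_row(prot, three)
  expect_equal(row$epitope_count, 3L)
  expect_equal(row$mean_cpr, 0.5)
  expect_equal(row$ed, 3 * 1.5 / 324)
  expect_equal(row$allele_count, 2L)

  # one core retained for two alleles: one epitope, coverage two,
  # affinity taken from the stronger allele
  dup <- rbind(core_row("P", "A", "AAAAAAAAA", 10, 0.8),
               core_row("P", "B", "AAAAAAAAA", 10, 0.2))
  row2 <- build_screening_row(prot, dup)
  expect_equal(row2$epitope_count, 1L)
  expect_equal(row2$allele_count, 2L)
  expect_equal(row2$mean_cpr, 0.2)
  expect_error(build_screening_row(prot, core_row("Q", "A", "X123", 1)),
               "belong")
  expect_error(build_screening_row(prot, core_row("P", "A", "AAAAAAAAA",
                                                  1, core_cpr = 1.2)),
               "core_cpr")
})

test_that("load_screening_table reads the packaged table and flags formula drift", {
  tab <- asn_table2(check_formula = FALSE)
  expect_equal(nrow(tab), 26L)
  expect_equal(tab$ed[tab$id == "WP_044373749.1"], 0.0027)
  expect_equal(tab$epitope_count[tab$id == "WP_044373749.1"], 3L)
  expect_equal(tab$allele_count[tab$id == "WP_044373749.1"], 4L)
  # lengths joined across accession-version spelling differences
  expect_equal(tab$length[tab$id == "WP_044373749.1"], 330L)
  expect_true(is.na(tab$length[tab$id == "Q9K4F5_ScAII"]))
  # printed ED values are not reproducible from the printed inputs
  expect_warning(asn_table2(), "differs from the ED formula")

  empty <- tempfile(fileext = ".tsv")
  writeLines("id\tepitope_number\tcpr_value\tallele_number\ted", empty)
  expect_error(load_screening_table(empty), "empty")
  badcols <- tempfile(fileext = ".tsv")
  writeLines(c("id\ted", "A\t0.1"), badcols)
  expect_error(load_screening_table(badcols), "missing column")
})

test_that("compare_to_reference returns ids strictly above the reference ED", {
  tab <- asn_table2(check_formula = FALSE)
  above <- compare_to_reference(tab, "P00805_EcAII")
  expect_setequal(above, c("WP_053609500.1", "WP_053610569.1", "EFL23513.1",
                           "WP_095730579.1", "WP_078513220.1",
                           "WP_052425051.1"))
  # sorted by descending ED
  expect_equal(above[1], "WP_053610569.1")
  expect_equal(tab$ed[match(above, tab$id)],
               sort(tab$ed[match(above, tab$id)], decreasing = TRUE))

  expect_equal(compare_to_reference(tab, "WP_053610569.1"), character(0))
  equal_two <- data.frame(id = c("A", "B"), epitope_count = 1L,
                          mean_cpr = 0.5, allele_count = 1L,
                          ed = 0.01, length = 100L)
  expect_equal(compare_to_reference(equal_two, "A"), character(0))
  expect_error(compare_to_reference(tab, "NOPE"), "not found")
})

test_that("select_candidates matches an exhaustive dominance oracle", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    rows <- data.frame(id = sprintf("C%02d", seq_len(n)),
                       epitope_count = sample(1:10, n, replace = TRUE),
                       mean_cpr = runif(n, 0, 1),
                       allele_count = sample(1:8, n, replace = TRUE),
                       ed = round(runif(n, 0.001, 0.02), 4),
                       length = 300L)
    anti <- data.frame(id = rows$id, probability = round(runif(n), 3))
    ref <- rows$id[n]
    rk <- select_candidates(rows, anti, ref)
    cand <- rows[rows$id != ref, ]
    crit <- cbind(cand$ed, cand$allele_count,
                  anti$probability[match(cand$id, anti$id)])
    expect_setequal(rk$pareto_front, cand$id[pareto_oracle(crit)])
    expect_true(all(rk$selected %in% rk$pareto_front))
    expect_false(ref %in% rk$selected)
  }
})

test_that("select_candidates handles dominance, degeneracy, and family restriction", {
  rows <- data.frame(id = c("A", "B", "C", "REF"),
                     epitope_count = 1L, mean_cpr = 0.5,
                     allele_count = c(2L, 5L, 6L, 5L),
                     ed = c(0.002, 0.01, 0.015, 0.011), length = 300L)
  anti <- data.frame(id = rows$id, probability = c(0.1, 0.5, 0.8, 0.6))
  rk <- select_candidates(rows, anti, "REF")
  expect_equal(rk$pareto_front, "A")          # A dominates B and C
  expect_equal(rk$ordered_ids[1], "A")

  same <- data.frame(id = c("A", "B", "REF"), epitope_count = 1L,
                     mean_cpr = 0.5, allele_count = 3L, ed = 0.01,
                     length = 300L)
  anti2 <- data.frame(id = same$id, probability = 0.5)
  rk2 <- select_candidates(same, anti2, "REF")
  expect_setequal(rk2$pareto_front, c("A", "B"))   # all candidates tie

  fams <- data.frame(id = c("A", "B", "C", "REF"),
                     family = c("PF00710.11", "PF06089.11", "PF06089.11",
                                "PF00710.11"))
  rk3 <- select_candidates(rows, anti, "REF", family_labels = fams,
                           restrict_family = "PF06089.11")
  expect_equal(rk3$selected, character(0))    # front member A is PF00710
  expect_equal(rk3$pareto_front, "A")

  expect_error(select_candidates(rows, anti[-1, ], "REF"), "A")
  expect_error(select_candidates(rows, anti, "NOPE"), "not found")
})

test_that("generate_screening_table plants extrema and round-trips", {
  path <- tempfile(fileext = ".tsv")
  df <- generate_screening_table(25, seed = 17, planted_min_id = "LOW",
                                 planted_max_id = "HIGH", path = path)
  tab <- load_screening_table(path)
  expect_equal(nrow(tab), 25L)
  expect_equal(tab$id[which.min(tab$ed)], "LOW")
  expect_equal(tab$id[which.max(tab$ed)], "HIGH")
  expect_equal(sum(tab$ed == min(tab$ed)), 1L)
  expect_equal(sum(tab$ed == max(tab$ed)), 1L)
  expect_equal(tab$ed, df$ed)

  single <- generate_screening_table(1, seed = 17, planted_min_id = "ONLY")
  expect_equal(single$id, "ONLY")

  expect_identical(generate_screening_table(10, seed = 3),
                   generate_screening_table(10, seed = 3))
})
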