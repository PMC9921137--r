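test_that("allele frequencies count copies and sum to one", {
  # 17 heterozygotes sharing two alleles: perfect 0.5/0.5 symmetry
  tab <- uniform_locus_table(17, 188, 200)
  p <- allele_frequencies(tab, "L1")
  expect_equal(unname(p), c(0.5, 0.5))
  expect_equal(names(p), c("188", "200"))
  # 16 x (a1,a2) + 1 x (a3,a4): copy-counting oracle
  p <- allele_frequencies(predominant_locus_table(), "L1")
  expect_equal(sort(unname(p), decreasing = TRUE),
    c(16 / 34, 16 / 34, 1 / 34, 1 / 34))
  expect_equal(sum(p), 1)
  # monomorphic
  p <- allele_frequencies(uniform_locus_table(3, 150, 150), "L1")
  expect_equal(unname(p), 1)
  # all-missing locus errors
  tab <- ssr_from_calls(matrix("", 2, 1,
    dimnames = list(c("a", "b"), "L1")))
  expect_error(allele_frequencies(tab, "L1"), "non-missing")
})

test_that("locus summary reproduces the published index values", {
  # single shared heterozygous genotype: the biallelic fixed-heterozygosity row
  s <- locus_summary(uniform_locus_table(17, 188, 200), "L1")
  expect_equal(s$Na, 2)
  expect_equal(c(s$ASR_min, s$ASR_max), c(188, 200))
  expect_equal(round_half_up(c(s$Ho, s$He, s$I, s$F, s$E)),
    c(1.00, 0.50, 0.69, -1.00, 1.00))
  # 94% predominant four-allele configuration
  s <- locus_summary(predominant_locus_table(), "L1")
  expect_equal(s$Na, 4)
  expect_equal(round_half_up(c(s$Ho, s$He, s$I, s$F, s$E)),
    c(1.00, 0.56, 0.92, -0.80, 0.83))
  # monomorphic degenerate limit
  s <- locus_summary(uniform_locus_table(3, 150, 150), "L1")
  expect_equal(c(s$Ho, s$He, s$I, s$E), c(0, 0, 0, 1))
  expect_true(is.na(s$F))
})

test_that("population summary matches the published per-locus column averages", {
  # the ten printed per-locus index values, loci as rows
  printed <- data.frame(
    Na = c(4, 4, 2, 2, 2, 2, 3, 4, 2, 4),
    Ho = c(1.00, 0.65, 1.00, 1.00, 1.00, 1.00, 1.00, 0.06, 1.00, 1.00),
    F = c(-0.80, -0.12, -1.00, -1.00, -1.00, -1.00, -0.88, 0.78, -1.00,
      -0.78))
  expect_equal(sum(printed$Na), 29)
  expect_equal(round_half_up(mean(printed$Ho)), 0.87)
  expect_equal(round_half_up(mean(printed$F)), -0.68)
  # the same aggregation done by summarize_population on a synthetic panel
  pop <- simulate_clonal_population(simulation_config(seed = 2))
  s <- summarize_population(pop$ssr)
  expect_equal(s$total_alleles, sum(s$per_locus$Na))
  for (k in c("Ho", "He", "I", "E")) {
    v <- s$per_locus[[k]]
    row <- s$summary[s$summary$index == k, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$se, stats::sd(v) / sqrt(length(v)))
  }
  fv <- s$per_locus$F[!is.na(s$per_locus$F)]
  expect_equal(s$summary[s$summary$index == "F", "mean"], mean(fv))
})

test_that("single-locus summary reports se = 0 with a warning", {
  expect_warning(s <- summarize_population(uniform_locus_table(5, 100, 104)),
    "single locus")
  expect_equal(s$summary$se, rep(0, 6))
})

test_that("indices equal a from-definition recomputation on random tables", {
  withr::local_seed(77)
  for (i in 1:60) {
    tab <- random_ssr_table(sample(2:4, 1), sample(1:3, 1), n_alleles = 3)
    for (lc in tab$loci) {
      got <- locus_summary(tab, lc)
      want <- naive_locus_indices(tab, lc)
      expect_equal(got$Na, want$Na)
      for (k in c("Ho", "He", "I", "E")) {
        expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
      }
      expect_equal(got$F, want$F, tolerance = 1e-12)
    }
  }
})

test_that("index invariants hold across random tables", {
  withr::local_seed(31)
  for (i in 1:40) {
    tab <- random_ssr_table(sample(2:8, 1), sample(1:4, 1),
      n_alleles = sample(2:4, 1))
    per <- suppressWarnings(summarize_population(tab))$per_locus
    expect_true(all(per$Ho >= 0 & per$Ho <= 1))
    expect_true(all(per$He >= 0 & per$He < 1))
    expect_true(all(per$I >= 0))
    expect_true(all(per$I <= log(per$Na) + 1e-12))
    expect_true(all(per$F <= 1 + 1e-12, na.rm = TRUE))
    expect_true(all(per$E > 0 & per$E <= 1 + 1e-12))
    expect_true(all((per$He == 0) == (per$Na == 1)))
  }
})

test_that("He and I are invariant under allele relabeling; E = 1 under uniform frequencies", {
  tab <- predominant_locus_table(major = c(128L, 134L), minor = c(120L, 126L))
  rel <- predominant_locus_table(major = c(300L, 210L), minor = c(144L, 180L))
  s1 <- locus_summary(tab, "L1")
  s2 <- locus_summary(rel, "L1")
  expect_equal(s1$He, s2$He)
  expect_equal(s1$I, s2$I)
  # equal allele frequencies give evenness exactly 1 for Na = 1..4
  expect_equal(locus_summary(uniform_locus_table(4, 100, 100), "L1")$E, 1)
  for (k in 2:4) {
    # k alleles, each at frequency 1/k: rotate genotypes around the pool
    pool <- 100L + 2L * seq_len(k)
    n <- 2 * k
    a1 <- matrix(pool[(seq_len(n) - 1) %% k + 1], n, 1,
      dimnames = list(paste0("s", 1:n), "L1"))
    a2 <- matrix(pool[seq_len(n) %% k + 1], n, 1,
      dimnames = list(paste0("s", 1:n), "L1"))
    tab <- ssr_table(a1, a2)
    p <- allele_frequencies(tab, "L1")
    expect_equal(unname(p), rep(1 / k, k))
    expect_equal(locus_summary(tab, "L1")$E, 1, tolerance = 1e-12)
  }
})

test_that("multilocus genotypes partition samples by identical profiles", {
  pop <- simulate_clonal_population(simulation_config(ssr_mutation_rate = 0,
    seed = 4))
  expect_equal(multilocus_genotypes(pop$ssr)$n_mlg, 1)
  # the clone-panel structure with identical groups {13,16}, {8,9,11},
  # {4,5,12,14}: counting gives 11 distinct profiles among 17
  ids <- paste0("G", 1:17)
  a1 <- matrix(100L, 17, 2, dimnames = list(ids, c("L1", "L2")))
  a2 <- matrix(110L, 17, 2, dimnames = list(ids, c("L1", "L2")))
  groups <- list(c(13, 16), c(8, 9, 11), c(4, 5, 12, 14))
  singletons <- setdiff(1:17, unlist(groups))
  for (k in seq_along(groups)) a2[groups[[k]], 1] <- 110L + 2L * k
  for (k in seq_along(singletons)) a2[singletons[k], 2] <- 130L + 2L * k
  mlg <- multilocus_genotypes(ssr_table(a1, a2))
  expect_equal(mlg$n_mlg, 11)
  sizes <- sort(unname(vapply(mlg$groups, length, integer(1))))
  expect_equal(sizes, c(rep(1L, 8), 2L, 3L, 4L))
  # two samples differing at exactly one locus are distinct MLGs
  tab <- ssr_from_calls(matrix(c("100/102", "100/102", "100/102", "100/104"),
    2, 2, dimnames = list(c("x", "y"), c("L1", "L2"))))
  expect_equal(multilocus_genotypes(tab)$n_mlg, 2)
})

test_that("missing-data handling in MLG matching: strict splits, lenient merges", {
  calls <- matrix(c("100/102", "100/102", "110/112", ""), 2, 2,
    dimnames = list(c("x", "y"), c("L1", "L2")))
  tab <- ssr_from_calls(calls)
  expect_equal(multilocus_genotypes(tab, missing = "strict")$n_mlg, 2)
  expect_equal(multilocus_genotypes(tab, missing = "lenient")$n_mlg, 1)
})
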