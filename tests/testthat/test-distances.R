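test_that("Prevosti distance matches hand-computed genotype cases", {
  # identical profiles
  tab <- ssr_from_calls(matrix(c("188/200", "188/200"), 2, 1,
    dimnames = list(c("x", "y"), "L1")))
  expect_equal(unclass(prevosti_distance(tab))["x", "y"], 0)
  # (A,B) vs (A,C): half of |0.5-0.5| + |0.5-0| + |0-0.5| = 0.5
  tab <- ssr_from_calls(matrix(c("100/102", "100/104"), 2, 1,
    dimnames = list(c("x", "y"), "L1")))
  expect_equal(unclass(prevosti_distance(tab))["x", "y"], 0.5)
  # disjoint homozygotes saturate the range
  tab <- ssr_from_calls(matrix(c("100/100", "102/102"), 2, 1,
    dimnames = list(c("x", "y"), "L1")))
  expect_equal(unclass(prevosti_distance(tab))["x", "y"], 1)
  # heterozygote vs one-shared homozygote: |1-0.5| + |0-0.5| over 2 = 0.5
  tab <- ssr_from_calls(matrix(c("100/102", "100/100"), 2, 1,
    dimnames = list(c("x", "y"), "L1")))
  expect_equal(unclass(prevosti_distance(tab))["x", "y"], 0.5)
})

test_that("Prevosti equals the mean of single-locus distances and ignores order/labels", {
  withr::local_seed(11)
  for (i in 1:20) {
    tab <- random_ssr_table(4, 3, n_alleles = 3)
    d <- prevosti_distance(tab)
    per_locus <- lapply(tab$loci, function(lc) {
      sub <- ssr_table(tab$a1[, lc, drop = FALSE],
        tab$a2[, lc, drop = FALSE])
      unclass(prevosti_distance(sub))
    })
    expect_equal(unclass(d), Reduce(`+`, per_locus) / length(per_locus),
      tolerance = 1e-12)
    # locus reordering leaves the distance unchanged
    perm <- sample(tab$loci)
    tab2 <- ssr_table(tab$a1[, perm, drop = FALSE],
      tab$a2[, perm, drop = FALSE])
    expect_equal(unclass(prevosti_distance(tab2)), unclass(d))
    # allele relabeling (order-preserving size shift) leaves it unchanged
    tab3 <- ssr_table(tab$a1 + 500L, tab$a2 + 500L)
    expect_equal(unclass(prevosti_distance(tab3)), unclass(d))
  }
})

test_that("missing loci are dropped pairwise with renormalization", {
  calls <- matrix(c("100/102", "100/102", "110/110", "", "", "120/122"),
    2, 3, dimnames = list(c("x", "y"), c("L1", "L2", "L3")))
  d <- prevosti_distance(ssr_from_calls(calls))
  expect_equal(unclass(d)["x", "y"], 0)  # only L1 shared, identical there
  # a pair sharing no locus is an error naming the pair
  calls <- matrix(c("100/102", "", "", "110/112"), 2, 2,
    dimnames = list(c("x", "y"), c("L1", "L2")))
  expect_error(prevosti_distance(ssr_from_calls(calls)), "'x' and 'y'")
})

test_that("Jaccard distance matches set-cardinality cases and excludes joint absences", {
  m <- rbind(x = c(1, 1, 0), y = c(1, 0, 1))
  colnames(m) <- paste0("B", 1:3)
  d <- jaccard_distance(band_matrix(m))
  expect_equal(unclass(d)["x", "y"], 1 - 1 / 3)
  # identical and disjoint profiles
  m <- rbind(x = c(1, 1, 0, 0), y = c(1, 1, 0, 0), z = c(0, 0, 1, 1))
  colnames(m) <- paste0("B", 1:4)
  d <- unclass(jaccard_distance(band_matrix(m)))
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 1)
  # appending joint-absence columns changes nothing
  m2 <- cbind(m, B5 = 0, B6 = 0)
  expect_equal(unclass(jaccard_distance(band_matrix(m2))), d)
  # both-empty pair: 0 by convention, with a warning
  m3 <- rbind(x = c(0, 0), y = c(0, 0))
  colnames(m3) <- c("B1", "B2")
  expect_warning(d3 <- jaccard_distance(band_matrix(m3)), "no band")
  expect_equal(unclass(d3)["x", "y"], 0)
})

test_that("Jaccard agrees with an established implementation on random matrices", {
  skip_if_not_installed("vegan")
  withr::local_seed(5)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    m <- matrix(rbinom(n * 10, 1, 0.5), n, 10,
      dimnames = list(paste0("s", 1:n), paste0("B", 1:10)))
    if (any(rowSums(m) == 0)) next
    mine <- as_dist(jaccard_distance(band_matrix(m)))
    ref <- vegan::vegdist(m, method = "jaccard", binary = TRUE)
    expect_equal(as.numeric(mine), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Gower distance reproduces its range-normalized cases", {
  # 2 samples always span the range
  x <- data.frame(t1 = c(0, 5), row.names = c("a", "b"))
  expect_equal(unclass(gower_distance(x, zscore = FALSE))["a", "b"], 1)
  # 3 samples, one trait 0/1/2
  x <- data.frame(t1 = c(0, 1, 2), row.names = c("a", "b", "c"))
  d <- unclass(gower_distance(x, zscore = FALSE))
  expect_equal(d["a", "c"], 1)
  expect_equal(d["a", "b"], 0.5)
  # z-scoring first does not change a single-trait Gower (affine invariance)
  expect_equal(unclass(gower_distance(x, zscore = TRUE)), d)
  # replicates are averaged per clone before the distance
  tt <- trait_table(data.frame(sample = rep(c("a", "b", "c"), each = 2),
    replicate = rep(1:2, 3), t1 = c(-1, 1, 0, 2, 1, 3)))
  d <- unclass(gower_distance(tt))  # clone means 0, 1, 2
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 1)
})

test_that("constant traits are dropped with a warning; all-constant errors", {
  x <- data.frame(t1 = c(1, 1, 1), t2 = c(0, 1, 3),
    row.names = c("a", "b", "c"))
  expect_warning(d <- gower_distance(x, zscore = FALSE), "constant")
  expect_equal(unclass(d)["a", "b"], 1 / 3)
  expect_error(suppressWarnings(
    gower_distance(data.frame(t1 = c(2, 2), row.names = c("a", "b")),
      zscore = FALSE)), "all traits")
})

test_that("all three distances satisfy the metric axioms on random instances", {
  withr::local_seed(21)
  for (i in 1:15) {
    tab <- random_ssr_table(sample(3:6, 1), sample(2:4, 1))
    dp <- unclass(prevosti_distance(tab))
    expect_true(all(dp >= 0 & dp <= 1))
    expect_equal(dp, t(dp))
    expect_equal(unname(diag(dp)), rep(0, nrow(dp)))
    expect_true(triangle_ok(dp))
    n <- sample(3:6, 1)
    m <- matrix(rbinom(n * 8, 1, 0.6), n, 8,
      dimnames = list(paste0("s", 1:n), paste0("B", 1:8)))
    if (all(rowSums(m) > 0)) {
      dj <- unclass(jaccard_distance(band_matrix(m)))
      expect_true(all(dj >= 0 & dj <= 1))
      expect_true(triangle_ok(dj))
    }
    x <- as.data.frame(matrix(rnorm(n * 3), n,
      dimnames = list(paste0("s", 1:n), paste0("t", 1:3))))
    dg <- unclass(gower_distance(x))
    expect_true(all(dg >= 0 & dg <= 1 + 1e-12))
    expect_equal(dg, t(dg))
  }
})
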