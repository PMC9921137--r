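# Fixture builders and independent brute-force oracles shared by the suite.
# Oracles deliberately avoid the package's own code paths.

# build an ssr_table from a character matrix of "a/b" calls ("" = missing)
ssr_from_calls <- function(calls) {
  a1 <- a2 <- matrix(NA_integer_, nrow(calls), ncol(calls),
    dimnames = dimnames(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(ncol(calls))) {
      if (!is.na(calls[i, j]) && calls[i, j] != "") {
        pr <- as.integer(strsplit(calls[i, j], "/")[[1]])
        a1[i, j] <- pr[1]; a2[i, j] <- pr[2]
      }
    }
  }
  ssr_table(a1, a2)
}

# n samples sharing one genotype at a single locus
uniform_locus_table <- function(n, allele_a, allele_b, locus = "L1") {
  ids <- paste0("G", seq_len(n))
  a1 <- matrix(as.integer(allele_a), n, 1, dimnames = list(ids, locus))
  a2 <- matrix(as.integer(allele_b), n, 1, dimnames = list(ids, locus))
  ssr_table(a1, a2)
}

# the 16 x (a1,a2) + 1 x (a3,a4) single-locus configuration
predominant_locus_table <- function(major = c(128L, 134L),
                                    minor = c(120L, 126L)) {
  ids <- paste0("G", 1:17)
  a1 <- matrix(c(rep(major[1], 16), minor[1]), 17, 1,
    dimnames = list(ids, "L1"))
  a2 <- matrix(c(rep(major[2], 16), minor[2]), 17, 1,
    dimnames = list(ids, "L1"))
  ssr_table(a1, a2)
}

# random genotype table: n samples x p loci, alleles drawn from a small pool
random_ssr_table <- function(n, p, n_alleles = 3, miss_prob = 0) {
  ids <- paste0("S", seq_len(n))
  loci <- paste0("L", seq_len(p))
  pool <- 100L + 2L * seq_len(n_alleles)
  a1 <- matrix(sample(pool, n * p, replace = TRUE), n, p,
    dimnames = list(ids, loci))
  a2 <- matrix(sample(pool, n * p, replace = TRUE), n, p,
    dimnames = list(ids, loci))
  if (miss_prob > 0) {
    na <- matrix(runif(n * p) < miss_prob, n, p)
    a1[na] <- NA_integer_; a2[na] <- NA_integer_
  }
  ssr_table(a1, a2)
}

# random symmetric nonnegative distance matrix with zero diagonal
random_dist <- function(n, max_d = 1) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2, 0.01, max_d)
  m <- m + t(m)
  labs <- paste0("S", seq_len(n))
  dimnames(m) <- list(labs, labs)
  dist_matrix(m)
}

# ---- oracles ------------------------------------------------------------

# per-locus diversity indices straight from the definitions, counting copies
naive_locus_indices <- function(tab, locus) {
  copies <- c(tab$a1[, locus], tab$a2[, locus])
  copies <- copies[!is.na(copies)]
  p <- as.numeric(table(copies)) / length(copies)
  ok <- !is.na(tab$a1[, locus])
  Ho <- sum(tab$a1[ok, locus] != tab$a2[ok, locus]) / sum(ok)
  He <- 1 - sum(p^2)
  I <- -sum(p * log(p))
  list(Na = length(p), Ho = Ho, He = He, I = I,
    F = if (He > 0) (He - Ho) / He else NA_real_,
    E = if (length(p) == 1) 1 else
      ((1 / sum(p^2)) - 1) / (exp(I) - 1))
}

# from-definition UPGMA: cluster sets, inter-cluster averages recomputed
# from the ORIGINAL matrix at every step (no linkage-update recursion);
# ties broken by smallest member label, as documented for upgma()
naive_upgma_heights <- function(d) {
  m <- unclass(d)
  clusters <- as.list(seq_len(nrow(m)))
  labs <- rownames(m)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        avg <- mean(m[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labs[clusters[[i]]]), min(labs[clusters[[j]]])))
        better <- avg < best_d ||
          (avg == best_d && (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) { best_d <- avg; best <- c(i, j); best_key <- key }
      }
    }
    heights <- c(heights, best_d / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# naive cophenetic: merge heights between cluster members, original matrix
naive_cophenetic <- function(d) {
  m <- unclass(d)
  n <- nrow(m)
  cm <- matrix(0, n, n, dimnames = dimnames(m))
  clusters <- as.list(seq_len(n))
  labs <- rownames(m)
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        avg <- mean(m[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labs[clusters[[i]]]), min(labs[clusters[[j]]])))
        better <- avg < best_d ||
          (avg == best_d && (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) { best_d <- avg; best <- c(i, j); best_key <- key }
      }
    }
    cm[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    cm[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  cm
}

lower_vec_of <- function(m) {
  m <- unclass(m)
  m[lower.tri(m)]
}

is_ultrametric <- function(m, tol = 1e-9) {
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (m[i, k] > max(m[i, j], m[j, k]) + tol) return(FALSE)
  }
  TRUE
}

triangle_ok <- function(m, tol = 1e-9) {
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (m[i, j] > m[i, k] + m[k, j] + tol) return(FALSE)
  }
  TRUE
}
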