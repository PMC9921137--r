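#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation between the lower triangles of
#' the two matrices (aligned by label, diagonal excluded). The null
#' distribution is built by jointly permuting the rows and columns of the
#' second matrix. The p-value uses the add-one rule,
#' p = (number of permuted statistics at least as extreme + 1)/(n_perm + 1),
#' so its resolution is 1/(n_perm + 1). With `exact = TRUE` (feasible for
#' about 8 labels or fewer) all n! permutations are enumerated instead and
#' p = (count of statistics at least as extreme)/n!, the identity
#' permutation included.
#'
#' @param d1,d2 [dist_matrix] objects with the same labels.
#' @param n_perm number of random permutations (default 9999).
#' @param alternative `"greater"` (concordance, default) or `"two.sided"`
#'   (on |r|).
#' @param seed integer seed for the permutation stream; `NULL` uses the
#'   current RNG state.
#' @param exact enumerate all permutations instead of sampling.
#' @return object of class `mantel_result`: list with `r_observed`,
#'   `p_value`, `n_permutations`, `alternative`, `seed`, `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999,
                        alternative = c("greater", "two.sided"),
                        seed = NULL, exact = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(d1, "dist_matrix"))
  d2 <- align_dist(d2, dist_labels(d1), "second distance matrix")
  n <- length(dist_labels(d1))
  m1 <- unclass(d1)
  m2 <- unclass(d2)
  lt <- which(lower.tri(m1), arr.ind = TRUE)
  v1 <- m1[lt]
  if (stats::sd(v1) == 0 || stats::sd(m2[lt]) == 0) {
    stop("constant half-matrix: Mantel statistic undefined", call. = FALSE)
  }
  # centred v1 reused across permutations
  v1c <- v1 - mean(v1)
  s1 <- sqrt(sum(v1c^2))
  stat <- function(perm) {
    v2 <- m2[cbind(perm[lt[, 1]], perm[lt[, 2]])]
    v2c <- v2 - mean(v2)
    s2 <- sqrt(sum(v2c^2))
    sum(v1c * v2c) / (s1 * s2)
  }
  r_obs <- stat(seq_len(n))
  meets <- function(r) {
    if (alternative == "greater") r >= r_obs - 1e-12
    else abs(r) >= abs(r_obs) - 1e-12
  }
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, stat, numeric(1))
    p <- sum(meets(rs)) / length(perms)
    n_used <- length(perms) - 1L
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (meets(stat(sample.int(n)))) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r_observed = r_obs, p_value = p, n_permutations = n_used,
    alternative = alternative, seed = seed, exact = exact),
    class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test: r = %.4f, p = %.4g (%s, %s permutations%s)\n",
    x$r_observed, x$p_value, x$alternative,
    format(x$n_permutations, big.mark = ","),
    if (x$exact) ", exhaustive" else ""))
  invisible(x)
}

all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Pairwise concordance table across marker systems
#'
#' For every pair of marker systems (e.g. SSR, dominant bands, quantitative
#' morphology) runs the Mantel test on the distance matrices (reported below
#' the diagonal) and on the cophenetic matrices of the UPGMA trees built from
#' them (above the diagonal) — the layout of a classic concordance table.
#'
#' @param systems named list; each element is a list with components
#'   `distance` (a [dist_matrix]) and optionally `tree` (a
#'   `clone_dendrogram`; built by [upgma] if absent). All systems must share
#'   sample labels.
#' @param n_perm permutations per test.
#' @param alternative passed to [mantel_test].
#' @param seed integer; each test uses a distinct sub-seed derived from it.
#' @return object of class `concordance_table`: list with matrices `r` and
#'   `p` (distance-based below, cophenetic-based above the diagonal, `NA` on
#'   it) and `tests` (long data.frame of all 2*C(k,2) results).
#' @export
concordance_table <- function(systems, n_perm = 9999,
                              alternative = c("greater", "two.sided"),
                              seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(is.list(systems), length(systems) >= 2,
    !is.null(names(systems)), all(names(systems) != ""))
  labs <- dist_labels(systems[[1]]$distance)
  sys <- lapply(systems, function(s) {
    d <- align_dist(s$distance, labs, "system distance matrix")
    tree <- if (!is.null(s$tree)) s$tree else upgma(d)
    coph <- align_dist(cophenetic_matrix(tree), labs, "cophenetic matrix")
    list(d = d, coph = coph)
  })
  k <- length(sys)
  nm <- names(systems)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  rows <- list()
  t_i <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      t_i <- t_i + 1L
      mt_d <- mantel_test(sys[[i]]$d, sys[[j]]$d, n_perm = n_perm,
        alternative = alternative, seed = stage_seed(seed, 2L * t_i))
      mt_c <- mantel_test(sys[[i]]$coph, sys[[j]]$coph, n_perm = n_perm,
        alternative = alternative, seed = stage_seed(seed, 2L * t_i + 1L))
      r[j, i] <- mt_d$r_observed; p[j, i] <- mt_d$p_value
      r[i, j] <- mt_c$r_observed; p[i, j] <- mt_c$p_value
      rows[[length(rows) + 1]] <- data.frame(system1 = nm[i],
        system2 = nm[j], matrices = "distance", r = mt_d$r_observed,
        p = mt_d$p_value, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(system1 = nm[i],
        system2 = nm[j], matrices = "cophenetic", r = mt_c$r_observed,
        p = mt_c$p_value, stringsAsFactors = FALSE)
    }
  }
  structure(list(r = r, p = p, tests = do.call(rbind, rows),
    n_permutations = n_perm, alternative = alternative, seed = seed),
    class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, digits = 3, ...) {
  k <- nrow(x$r)
  out <- matrix("-", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        out[i, j] <- sprintf("%.*f (%.2g)", digits, x$r[i, j], x$p[i, j])
      }
    }
  }
  cat("Concordance (below diagonal: distance matrices; above: cophenetic):\n")
  print(out, quote = FALSE)
  cat(sprintf("Mantel test, %d permutations, alternative = %s\n",
    x$n_permutations, x$alternative))
  invisible(x)
}
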