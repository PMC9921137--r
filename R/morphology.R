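#' Derived bunch and berry-composition traits
#'
#' Adds, where the base columns are present: the bunch compactness index
#' `compactness_index` = berries per bunch / total rachis length (berries/cm)
#' and the ripeness ratio `tss_ta_ratio` = total soluble solids (degrees
#' Brix) / titratable acidity (g/L tartaric acid). Both are computed per
#' observation, then any per-clone summary averages the per-observation
#' ratios (a ratio of clone means is not the same number). Observations with
#' a zero denominator are flagged: the derived value is set `NA` with a
#' warning.
#'
#' @param tt a [trait_table].
#' @param berries,rachis,tss,ta column names of the base traits.
#' @return the [trait_table] with derived columns appended.
#' @export
derive_traits <- function(tt, berries = "berries_per_bunch",
                          rachis = "rachis_length_cm", tss = "tss_brix",
                          ta = "ta_g_l") {
  stopifnot(inherits(tt, "trait_table"))
  made <- character()
  if (all(c(berries, rachis) %in% names(tt))) {
    zero <- tt[[rachis]] == 0
    if (any(zero, na.rm = TRUE)) {
      warning(sprintf("%d observation(s) with zero rachis length excluded from compactness index",
        sum(zero, na.rm = TRUE)))
    }
    tt$compactness_index <- ifelse(zero, NA_real_,
      tt[[berries]] / tt[[rachis]])
    made <- c(made, "compactness_index")
  }
  if (all(c(tss, ta) %in% names(tt))) {
    zero <- tt[[ta]] == 0
    if (any(zero, na.rm = TRUE)) {
      warning(sprintf("%d observation(s) with zero titratable acidity excluded from TSS/TA",
        sum(zero, na.rm = TRUE)))
    }
    tt$tss_ta_ratio <- ifelse(zero, NA_real_, tt[[tss]] / tt[[ta]])
    made <- c(made, "tss_ta_ratio")
  }
  if (length(made) == 0) {
    warning("no derivable trait: required base columns absent")
  }
  trait_table(as.data.frame(tt))
}

#' Potential fertility index
#'
#' Mean number of bunches per shoot, per clone.
#'
#' @param tt a [trait_table] with a `bunches_per_shoot` column.
#' @return named numeric vector (clone -> mean bunches per shoot).
#' @export
fertility_index <- function(tt, bunches = "bunches_per_shoot") {
  stopifnot(inherits(tt, "trait_table"))
  if (!bunches %in% names(tt)) {
    stop(sprintf("column '%s' absent", bunches), call. = FALSE)
  }
  tapply(tt[[bunches]], tt$sample, mean, na.rm = TRUE)
}

#' Coefficient of variation among clone means
#'
#' 100 * sd / mean with the n-1 denominator, the conventional among-clone
#' C.V. row of a trait table.
#'
#' @param clone_means numeric vector of per-clone means (length >= 2).
#' @return percentage.
#' @export
cv_percent <- function(clone_means) {
  clone_means <- clone_means[!is.na(clone_means)]
  if (length(clone_means) < 2) {
    stop("need at least 2 clone means", call. = FALSE)
  }
  m <- mean(clone_means)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(clone_means) / m
}

#' One-way ANOVA with Duncan's multiple range grouping letters
#'
#' Fits a one-way fixed-effects ANOVA of `values` on `groups` (via
#' [stats::aov]) and separates the group means with Duncan's multiple range
#' test: means are sorted and a pair spanning p ranked means differs when its
#' difference exceeds the critical range
#' q(1 - (1-alpha)^(p-1), p, df_error) * sqrt(MSE / n_h), with n_h the
#' harmonic mean group size for unbalanced data. The protected stepwise rule
#' applies: a range contained in a non-significant wider range is declared
#' non-significant. Letters are assigned so that two groups share a letter
#' iff they are not separated.
#'
#' @param values numeric response.
#' @param groups group labels (clone ids).
#' @param alpha significance level (default 0.05).
#' @return object of class `anova_duncan`: list with `F`, `p_value`,
#'   `df`, `means` (data.frame group/n/mean/se/letters, sorted by descending
#'   mean) and `degenerate` (TRUE when the within-group variance is zero).
#' @export
anova_duncan <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (min(table(groups)) < 2) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  an <- withCallingHandlers(stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  Fv <- an["groups", "F value"]
  pv <- an["groups", "Pr(>F)"]
  ns <- table(groups)
  means <- tapply(values, groups, mean)
  ses <- tapply(values, groups, function(v) stats::sd(v) / sqrt(length(v)))
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]; ses <- ses[ord]; ns <- ns[ord]
  k <- length(means)
  degenerate <- !is.finite(mse) ||
    mse <= 1e-12 * (stats::var(values) + .Machine$double.xmin)
  if (degenerate) {
    warning("zero within-group variance: ANOVA degenerate, letters from exact equality of means")
    sep <- outer(means, means, function(a, b) a != b)
  } else {
    n_h <- k / sum(1 / ns)  # harmonic mean group size
    # critical range for a span of p ranked means
    # protection level (1-alpha)^(p-1) is the confidence level of the
    # studentized-range quantile for a span of p means
    crit <- vapply(2:k, function(p) {
      stats::qtukey((1 - alpha)^(p - 1), p, dfe) * sqrt(mse / n_h)
    }, numeric(1))
    # raw significance per span, then protect: a pair inside any
    # non-significant containing range is non-significant
    sep <- matrix(FALSE, k, k)
    nonsig_span <- function(a, b) {
      abs(means[a] - means[b]) <= crit[(b - a + 1) - 1]
    }
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        covered <- FALSE
        for (aa in seq_len(a)) {
          for (bb in b:k) {
            if (nonsig_span(aa, bb)) { covered <- TRUE; break }
          }
          if (covered) break
        }
        sep[a, b] <- sep[b, a] <- !covered
      }
    }
  }
  letters_vec <- range_letters(sep)
  structure(list(F = Fv, p_value = pv, df = c(an["groups", "Df"], dfe),
    alpha = alpha, degenerate = degenerate,
    means = data.frame(group = names(means), n = as.integer(ns),
      mean = as.numeric(means), se = as.numeric(ses),
      letters = letters_vec, stringsAsFactors = FALSE)),
    class = "anova_duncan")
}

# letter display from a separation matrix over means sorted descending:
# maximal runs of mutually non-separated consecutive means get one letter
range_letters <- function(sep) {
  k <- nrow(sep)
  runs <- list()
  for (a in seq_len(k)) {
    b <- a
    while (b < k && !sep[a, b + 1]) b <- b + 1
    runs[[length(runs) + 1]] <- a:b
  }
  # drop runs contained in an earlier maximal run
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i != j && keep[j] && all(runs[[i]] %in% runs[[j]]) &&
          length(runs[[i]]) < length(runs[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  runs <- runs[keep]
  out <- character(k)
  for (i in seq_along(runs)) {
    lt <- letters[(i - 1) %% 26 + 1]
    if (i > 26) lt <- paste0(lt, (i - 1) %/% 26)
    out[runs[[i]]] <- paste0(out[runs[[i]]], lt)
  }
  out
}

#' @export
print.anova_duncan <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
    x$df[1], x$df[2], x$F, x$p_value))
  if (x$degenerate) cat("(degenerate: zero within-group variance)\n")
  cat(sprintf("Duncan grouping at alpha = %g:\n", x$alpha))
  print(x$means, row.names = FALSE, ...)
  invisible(x)
}

#' Correlation-matrix PCA of clone trait means
#'
#' Principal component analysis of standardized clone means (i.e. of the
#' trait correlation matrix) via [stats::prcomp]. Components with eigenvalue
#' above `tol` are retained; percent variance is relative to the sum of
#' retained eigenvalues. Variable-component correlations (loading *
#' sqrt(eigenvalue)) carry two-sided significance codes from a t test on r
#' with n - 2 degrees of freedom.
#'
#' @param clone_means data.frame/matrix of clone means (rows = clones) or a
#'   replicated [trait_table] (averaged first).
#' @param variables trait columns to use (default: all).
#' @param tol eigenvalue retention threshold.
#' @return object of class `pca_traits`: list with `eigenvalues`,
#'   `variance_pct`, `cumulative_pct`, `correlations`, `p_values`, `scores`,
#'   `n`.
#' @export
pca_on_traits <- function(clone_means, variables = NULL, tol = 1e-9) {
  if (inherits(clone_means, "trait_table")) {
    clone_means <- clone_trait_means(clone_means)
  }
  x <- as.matrix(as.data.frame(clone_means))
  if (!is.null(variables)) {
    missing_v <- setdiff(variables, colnames(x))
    if (length(missing_v)) {
      stop(sprintf("variables absent from table: %s",
        paste(missing_v, collapse = ", ")), call. = FALSE)
    }
    x <- x[, variables, drop = FALSE]
  }
  if (nrow(x) < 3) stop("need at least 3 clones for PCA", call. = FALSE)
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping constant variable(s): %s",
      paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  retain <- eig > tol
  eig <- eig[retain]
  pct <- 100 * eig / sum(eig)
  corr <- sweep(pc$rotation[, retain, drop = FALSE], 2, sqrt(eig), "*")
  n <- nrow(x)
  tstat <- corr * sqrt((n - 2) / pmax(1 - corr^2, 1e-300))
  pvals <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  colnames(corr) <- colnames(pvals) <- paste0("Dim.", seq_len(sum(retain)))
  structure(list(eigenvalues = eig, variance_pct = pct,
    cumulative_pct = cumsum(pct),
    correlations = corr, p_values = pvals,
    scores = pc$x[, retain, drop = FALSE], n = n),
    class = "pca_traits")
}

#' @export
print.pca_traits <- function(x, ...) {
  cat("Correlation-matrix PCA\n")
  tab <- data.frame(eigenvalue = round(x$eigenvalues, 3),
    variance_pct = round(x$variance_pct, 1),
    cumulative_pct = round(x$cumulative_pct, 1))
  rownames(tab) <- paste0("Dim.", seq_along(x$eigenvalues))
  print(tab, ...)
  invisible(x)
}

#' Percent and cumulative variance from eigenvalues
#'
#' Helper for reading a table of principal-component eigenvalues: percent of
#' variance per component relative to their sum, and the cumulative percent.
#'
#' @param eigenvalues nonnegative numeric vector.
#' @return data.frame with `component`, `eigenvalue`, `variance_pct`,
#'   `cumulative_pct`.
#' @export
variance_explained <- function(eigenvalues) {
  if (any(eigenvalues < 0)) stop("eigenvalues must be nonnegative",
    call. = FALSE)
  pct <- 100 * eigenvalues / sum(eigenvalues)
  data.frame(component = seq_along(eigenvalues), eigenvalue = eigenvalues,
    variance_pct = pct, cumulative_pct = cumsum(pct))
}
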