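#' Prevosti distance between individual SSR profiles
#'
#' For two samples, each locus contributes half the summed absolute
#' difference of the individuals' within-locus allele frequency vectors
#' (a homozygote carries frequency 1 on its allele, a heterozygote 0.5/0.5);
#' the distance is the mean contribution over the loci at which both samples
#' have calls. Loci missing in either sample are dropped pairwise and the
#' mean renormalized by the number m of shared loci. Ranges 0 to 1.
#'
#' @param tab an [ssr_table] with at least 2 samples.
#' @return a [dist_matrix].
#' @examples
#' a1 <- matrix(c(188L, 188L), 2, 1, dimnames = list(c("x", "y"), "L1"))
#' a2 <- matrix(c(200L, 204L), 2, 1, dimnames = list(c("x", "y"), "L1"))
#' prevosti_distance(ssr_table(a1, a2))  # shares one of two alleles -> 0.5
#' @export
prevosti_distance <- function(tab) {
  stopifnot(inherits(tab, "ssr_table"))
  n <- length(tab$samples)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(tab$samples, tab$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !(is.na(tab$a1[i, ]) | is.na(tab$a1[j, ]))
      m <- sum(shared)
      if (m == 0) {
        stop(sprintf(
          "samples '%s' and '%s' share no non-missing locus: distance undefined",
          tab$samples[i], tab$samples[j]), call. = FALSE)
      }
      contrib <- vapply(which(shared), function(l) {
        alleles <- unique(c(tab$a1[i, l], tab$a2[i, l],
          tab$a1[j, l], tab$a2[j, l]))
        px <- (as.numeric(alleles == tab$a1[i, l]) +
               as.numeric(alleles == tab$a2[i, l])) / 2
        py <- (as.numeric(alleles == tab$a1[j, l]) +
               as.numeric(alleles == tab$a2[j, l])) / 2
        sum(abs(px - py)) / 2
      }, numeric(1))
      d[i, j] <- d[j, i] <- sum(contrib) / m
    }
  }
  dist_matrix(d)
}

#' Jaccard distance between dominant band profiles
#'
#' d(x, y) = 1 - |x intersect y| / |x union y| over the bands present in at
#' least one of the two samples; bands absent in both are excluded by
#' definition. A pair of all-absent profiles gets distance 0 (identical
#' emptiness) with a warning.
#'
#' @param bands a [band_matrix] with at least 2 samples.
#' @return a [dist_matrix].
#' @export
jaccard_distance <- function(bands) {
  stopifnot(inherits(bands, "band_matrix"))
  m <- unclass(bands)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  inter <- m %*% t(m)
  tot <- rowSums(m)
  uni <- outer(tot, tot, "+") - inter
  d <- ifelse(uni > 0, 1 - inter / uni, 0)
  if (any(uni[lower.tri(uni)] == 0)) {
    warning("pair(s) with no band present in either sample: distance set to 0")
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  dist_matrix(d)
}

#' Gower distance on (optionally Z-scored) clone trait means
#'
#' Replicates are first averaged per sample; each trait is then standardized
#' to zero mean and unit standard deviation across samples (when `zscore` is
#' `TRUE`) and the Gower distance is the mean over traits of the absolute
#' difference divided by the trait's range across samples. Constant traits
#' carry no information under range normalization and are dropped with a
#' warning.
#'
#' @param traits a [trait_table] (replicated) or a data.frame of one row per
#'   sample with sample row names.
#' @param zscore standardize traits before range normalization.
#' @return a [dist_matrix].
#' @export
gower_distance <- function(traits, zscore = TRUE) {
  if (inherits(traits, "trait_table")) {
    x <- clone_trait_means(traits)
  } else {
    x <- as.data.frame(traits)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  keep <- apply(x, 2, function(v) max(v) > min(v))
  if (!all(keep)) {
    warning(sprintf("dropping constant trait(s): %s",
      paste(colnames(x)[!keep], collapse = ", ")))
  }
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) stop("all traits are constant: Gower distance undefined",
    call. = FALSE)
  if (zscore) x <- scale(x)
  rng <- apply(x, 2, function(v) max(v) - min(v))
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(abs(x[i, ] - x[j, ]) / rng)
    }
  }
  dist_matrix(d)
}
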