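#' Allele frequencies at one microsatellite locus
#'
#' Frequencies are computed over the 2 x (non-missing samples) allele copies
#' at the locus and sum to 1.
#'
#' @param tab an [ssr_table].
#' @param locus locus label.
#' @return named numeric vector (allele size -> frequency), sizes ascending.
#' @export
allele_frequencies <- function(tab, locus) {
  stopifnot(inherits(tab, "ssr_table"))
  if (!locus %in% tab$loci) {
    stop(sprintf("unknown locus '%s'", locus), call. = FALSE)
  }
  sizes <- c(tab$a1[, locus], tab$a2[, locus])
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0) {
    stop(sprintf("locus '%s' has no non-missing calls", locus), call. = FALSE)
  }
  counts <- table(sizes)
  p <- as.numeric(counts) / sum(counts)
  names(p) <- names(counts)
  p
}

#' Per-locus diversity indices
#'
#' Computes the standard per-locus summary for a codominant marker in a
#' (possibly clonal) population: number of alleles Na, allelic size range,
#' observed heterozygosity Ho (fraction of non-missing samples carrying two
#' distinct alleles), expected heterozygosity He = 1 - sum(p^2) (no
#' small-sample correction), Shannon index I = -sum(p log p), Wright's
#' fixation index F = (He - Ho)/He (undefined, `NA`, when He = 0), and
#' Stoddart-Taylor evenness E = ((1/lambda) - 1)/(exp(H) - 1) with
#' lambda = sum(p^2) and H = I, taken as 1 for a monomorphic locus (its
#' 0/0 limit). Strongly negative F is the signature of fixed heterozygosity
#' in clonally propagated material.
#'
#' @param tab an [ssr_table].
#' @param locus locus label.
#' @return one-row data.frame: `locus`, `Na`, `ASR_min`, `ASR_max`, `Ho`,
#'   `He`, `I`, `F`, `E`.
#' @examples
#' a1 <- matrix(188L, 17, 1, dimnames = list(paste0("G", 1:17), "VRZAG21"))
#' a2 <- matrix(200L, 17, 1, dimnames = list(paste0("G", 1:17), "VRZAG21"))
#' locus_summary(ssr_table(a1, a2), "VRZAG21")
#' @export
locus_summary <- function(tab, locus) {
  p <- allele_frequencies(tab, locus)
  sizes <- as.integer(names(p))
  ok <- !is.na(tab$a1[, locus])
  het <- tab$a1[ok, locus] != tab$a2[ok, locus]
  Ho <- mean(het)
  lambda <- sum(p^2)
  He <- 1 - lambda
  I <- -sum(p * log(p))
  F <- if (He > 0) (He - Ho) / He else NA_real_
  E <- if (length(p) == 1) 1 else ((1 / lambda) - 1) / (exp(I) - 1)
  data.frame(locus = locus, Na = length(p),
    ASR_min = min(sizes), ASR_max = max(sizes),
    Ho = Ho, He = He, I = I, F = F, E = E,
    stringsAsFactors = FALSE)
}

#' Population-level diversity summary over all loci
#'
#' Applies [locus_summary] to every locus and reports the total allele count
#' and, for each index, the mean and its standard error (sd / sqrt(n loci)).
#' The fixation index is averaged over the loci where it is defined. With a
#' single locus the standard error is reported as 0 with a warning.
#'
#' @param tab an [ssr_table].
#' @return list with `per_locus` (data.frame, one row per locus),
#'   `summary` (data.frame: index, mean, se, n) and `total_alleles`.
#' @export
summarize_population <- function(tab) {
  stopifnot(inherits(tab, "ssr_table"))
  if (length(tab$loci) < 1) stop("table has no loci", call. = FALSE)
  per <- do.call(rbind, lapply(tab$loci, function(l) locus_summary(tab, l)))
  if (length(tab$loci) == 1) {
    warning("single locus: standard errors reported as 0")
  }
  idx <- c("Na", "Ho", "He", "I", "F", "E")
  summ <- do.call(rbind, lapply(idx, function(k) {
    v <- per[[k]]
    v <- v[!is.na(v)]
    se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    data.frame(index = k, mean = mean(v), se = se, n = length(v),
      stringsAsFactors = FALSE)
  }))
  list(per_locus = per, summary = summ, total_alleles = sum(per$Na))
}

#' Multilocus genotype (MLG) assignment
#'
#' Two samples share a multilocus genotype iff their calls agree at every
#' locus. In the default `"strict"` mode a missing call matches nothing, so
#' samples with missing data are never merged; in `"lenient"` mode a missing
#' call is compatible with any call at that locus (samples are merged
#' greedily in input order). MLG ids are numbered by first occurrence.
#'
#' @param tab an [ssr_table].
#' @param missing `"strict"` or `"lenient"`.
#' @return list with `assignment` (named integer vector sample -> MLG id),
#'   `groups` (list of character vectors of samples per MLG) and `n_mlg`.
#' @export
multilocus_genotypes <- function(tab, missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  stopifnot(inherits(tab, "ssr_table"))
  n <- length(tab$samples)
  key <- function(i) paste(ifelse(is.na(tab$a1[i, ]), "?",
    paste0(tab$a1[i, ], "/", tab$a2[i, ])), collapse = "|")
  if (missing == "strict") {
    keys <- vapply(seq_len(n), key, character(1))
    # a sample with any missing call never matches another sample
    has_na <- apply(is.na(tab$a1), 1, any)
    keys[has_na] <- paste0(keys[has_na], "#", seq_len(n)[has_na])
    ids <- match(keys, unique(keys))
  } else {
    ids <- integer(n)
    next_id <- 0L
    compatible <- function(i, j) {
      ok <- !(is.na(tab$a1[i, ]) | is.na(tab$a1[j, ]))
      all(tab$a1[i, ok] == tab$a1[j, ok] & tab$a2[i, ok] == tab$a2[j, ok])
    }
    for (i in seq_len(n)) {
      hit <- 0L
      for (j in seq_len(i - 1L)) {
        if (compatible(i, j)) { hit <- ids[j]; break }
      }
      if (hit == 0L) { next_id <- next_id + 1L; hit <- next_id }
      ids[i] <- hit
    }
  }
  names(ids) <- tab$samples
  groups <- split(tab$samples, ids)
  names(groups) <- paste0("MLG", names(groups))
  list(assignment = ids, groups = groups, n_mlg = length(unique(ids)))
}

#' Round half-up for report display
#'
#' Base R rounds half-to-even; diversity tables are conventionally printed
#' with halves rounded away from zero (e.g. 0.565 -> 0.57).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
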