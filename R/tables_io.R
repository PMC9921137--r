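#' Dominant band presence/absence matrix
#'
#' Binary matrix of samples x markers for dominant fingerprinting systems
#' (e.g. retrotransposon-microsatellite amplified polymorphism bands scored
#' from gels). Absence is informative for dominant markers, so missing values
#' are not allowed.
#'
#' @param presence numeric/integer matrix of 0/1 with sample row names and
#'   band column names.
#' @return an object of class `band_matrix`.
#' @export
band_matrix <- function(presence) {
  if (!is.matrix(presence)) stop("presence must be a matrix", call. = FALSE)
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    stop("band matrix must carry sample and band names", call. = FALSE)
  }
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence))) {
    stop("duplicate sample or band ids", call. = FALSE)
  }
  if (any(is.na(presence)) || !all(presence %in% c(0, 1))) {
    bad <- which(is.na(presence) | !(presence %in% c(0, 1)), arr.ind = TRUE)[1, ]
    stop(sprintf("band cell (%s, %s) is not 0/1: '%s'",
      rownames(presence)[bad[1]], colnames(presence)[bad[2]],
      presence[bad[1], bad[2]]), call. = FALSE)
  }
  storage.mode(presence) <- "integer"
  class(presence) <- c("band_matrix", "matrix", "array")
  presence
}

#' Read / write a band matrix as CSV
#'
#' CSV layout: a `sample` column then one 0/1 column per band.
#'
#' @param path file path.
#' @param bm a [band_matrix].
#' @return `read_band_matrix` returns a [band_matrix].
#' @export
read_band_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) {
    stop("band CSV needs a 'sample' column", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "sample")])
  rownames(m) <- df$sample
  suppressWarnings(storage.mode(m) <- "double")
  band_matrix(m)
}

#' @rdname read_band_matrix
#' @export
write_band_matrix <- function(bm, path) {
  stopifnot(inherits(bm, "band_matrix"))
  df <- data.frame(sample = rownames(bm), unclass(bm), check.names = FALSE,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quantitative trait table
#'
#' Long-format table of replicated quantitative measurements: one row per
#' (sample, replicate) with named numeric trait columns (e.g. berries per
#' bunch, rachis length in cm, soluble solids in degrees Brix).
#'
#' @param df data.frame with columns `sample`, `replicate` and at least one
#'   numeric trait column.
#' @return a `trait_table` (a validated data.frame).
#' @export
trait_table <- function(df) {
  if (!is.data.frame(df)) stop("trait table must be a data.frame",
    call. = FALSE)
  if (!all(c("sample", "replicate") %in% names(df))) {
    stop("trait table needs 'sample' and 'replicate' columns", call. = FALSE)
  }
  traits <- setdiff(names(df), c("sample", "replicate"))
  if (length(traits) == 0) stop("no trait columns", call. = FALSE)
  if (anyDuplicated(traits)) stop("duplicate trait names", call. = FALSE)
  for (tr in traits) {
    if (!is.numeric(df[[tr]])) {
      stop(sprintf("trait '%s' is not numeric", tr), call. = FALSE)
    }
  }
  df$sample <- as.character(df$sample)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' @rdname trait_table
#' @param x object to test.
#' @export
trait_names <- function(x) setdiff(names(x), c("sample", "replicate"))

#' Read / write a trait table as CSV
#'
#' @param path file path.
#' @param tt a [trait_table].
#' @export
read_trait_table <- function(path) {
  trait_table(utils::read.csv(path, check.names = FALSE,
    stringsAsFactors = FALSE))
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(tt, path) {
  stopifnot(inherits(tt, "trait_table"))
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-clone trait means over replicates
#'
#' @param tt a [trait_table].
#' @return data.frame with one row per sample: mean of each trait over its
#'   replicates (row names = sample ids).
#' @export
clone_trait_means <- function(tt) {
  stopifnot(inherits(tt, "trait_table"))
  traits <- trait_names(tt)
  ag <- stats::aggregate(tt[traits], by = list(sample = tt$sample),
    FUN = mean, na.rm = TRUE)
  ag <- ag[match(unique(tt$sample), ag$sample), , drop = FALSE]
  rownames(ag) <- ag$sample
  ag$sample <- NULL
  ag
}
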