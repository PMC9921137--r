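#' Labelled distance matrix
#'
#' A `dist_matrix` is a square, symmetric, nonnegative numeric matrix with a
#' zero diagonal and unique sample labels. It is the shared currency of all
#' distance computations in the package (Prevosti, Jaccard, Gower) and of
#' cophenetic matrices extracted from dendrograms.
#'
#' @param x square numeric matrix with identical row and column names, or an
#'   object of class [stats::dist] with labels.
#' @param tol tolerance for the symmetry and zero-diagonal checks.
#' @return an object of class `dist_matrix` (a plain labelled matrix).
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' d <- dist_matrix(m)
#' dist_labels(d)
#' @export
dist_matrix <- function(x, tol = 1e-9) {
  if (inherits(x, "dist")) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("distance matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) != ncol(x)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  labs <- rownames(x)
  if (is.null(labs) || is.null(colnames(x))) {
    stop("distance matrix must carry row and column labels", call. = FALSE)
  }
  if (!identical(labs, colnames(x))) {
    stop("row and column labels differ", call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate labels in distance matrix", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("distance matrix contains non-finite values", call. = FALSE)
  }
  asym <- max(abs(x - t(x)))
  if (asym > tol) {
    idx <- which(abs(x - t(x)) == asym, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "distance matrix is asymmetric beyond tolerance at (%s, %s): %g vs %g",
      labs[idx[1]], labs[idx[2]], x[idx[1], idx[2]], x[idx[2], idx[1]]
    ), call. = FALSE)
  }
  if (max(abs(diag(x))) > tol) {
    bad <- which.max(abs(diag(x)))
    stop(sprintf("nonzero diagonal at %s: %g", labs[bad], diag(x)[bad]),
      call. = FALSE)
  }
  if (min(x) < -tol) {
    stop("negative distances are not allowed", call. = FALSE)
  }
  x <- (x + t(x)) / 2
  diag(x) <- 0
  x[x < 0] <- 0
  class(x) <- c("dist_matrix", "matrix", "array")
  x
}

#' @rdname dist_matrix
#' @export
dist_labels <- function(x) rownames(x)

#' @export
print.dist_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Distance matrix: %d samples\n", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Convert a dist_matrix to a stats::dist object
#'
#' @param m a [dist_matrix].
#' @return a [stats::dist] object.
#' @export
as_dist <- function(m) {
  stopifnot(inherits(m, "dist_matrix"))
  stats::as.dist(unclass(m))
}

# lower-triangle vector in a fixed (column-major) order, diagonal excluded
lower_vec <- function(m) {
  m <- unclass(m)
  m[lower.tri(m)]
}

# reorder a dist_matrix to a given label order, erroring on mismatch
align_dist <- function(m, labels, what = "distance matrix") {
  if (!setequal(dist_labels(m), labels) ||
      length(dist_labels(m)) != length(labels)) {
    stop(sprintf("labels of %s do not match: expected {%s}, found {%s}",
      what, paste(labels, collapse = ","),
      paste(dist_labels(m), collapse = ",")), call. = FALSE)
  }
  dist_matrix(unclass(m)[labels, labels, drop = FALSE])
}

#' Read and write labelled distance matrices
#'
#' CSV is a square labelled table (header row of labels, first column of
#' labels). The PHYLIP square dialect has the number of samples on the first
#' line followed by one row per sample: label then n values. Both formats
#' round-trip losslessly at full double precision.
#'
#' @param d a [dist_matrix].
#' @param path file path.
#' @param format `"csv"` or `"phylip_square"`.
#' @return `read_distance_matrix` returns a [dist_matrix];
#'   `write_distance_matrix` returns `path` invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("csv", "phylip_square")) {
  format <- match.arg(format)
  stopifnot(inherits(d, "dist_matrix"))
  m <- unclass(d)
  if (format == "csv") {
    df <- data.frame(sample = rownames(m),
      format(m, digits = 17, trim = TRUE, scientific = FALSE),
      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(rownames(m)[i],
        format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
        collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, format = c("csv", "phylip_square")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE,
      stringsAsFactors = FALSE)
    labs <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- labs
    if (!identical(colnames(m), labs)) {
      stop("distance CSV header labels do not match row labels", call. = FALSE)
    }
  } else {
    lines <- readLines(path)
    n <- as.integer(lines[1])
    if (is.na(n) || length(lines) < n + 1) {
      stop("malformed PHYLIP matrix: bad sample count", call. = FALSE)
    }
    rows <- strsplit(trimws(lines[2:(n + 1)]), "[ \t]+")
    labs <- vapply(rows, `[`, character(1), 1)
    m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
    dimnames(m) <- list(labs, labs)
  }
  dist_matrix(m)
}
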