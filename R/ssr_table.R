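#' Codominant SSR genotype table
#'
#' Holds, for each sample and microsatellite locus, an unordered pair of
#' positive integer allele sizes (bp). Alleles are stored in sorted order per
#' cell so a homozygote is a repeated size; a missing call is a pair of `NA`s.
#' Internally two integer matrices (`allele1 <= allele2`) share the sample
#' and locus dimnames.
#'
#' @param allele1,allele2 integer matrices (samples x loci) with identical
#'   dimnames; cells may be `NA` (both alleles must then be `NA`).
#' @return an object of class `ssr_table` with elements `samples`, `loci`,
#'   `a1`, `a2`.
#' @examples
#' a <- matrix(188L, 2, 1, dimnames = list(c("s1", "s2"), "VVS2"))
#' b <- matrix(200L, 2, 1, dimnames = list(c("s1", "s2"), "VVS2"))
#' tab <- ssr_table(a, b)
#' @export
ssr_table <- function(allele1, allele2) {
  if (!is.matrix(allele1) || !is.matrix(allele2) ||
      !identical(dim(allele1), dim(allele2))) {
    stop("allele1 and allele2 must be matrices of identical shape",
      call. = FALSE)
  }
  if (is.null(rownames(allele1)) || is.null(colnames(allele1))) {
    stop("allele matrices must carry sample and locus names", call. = FALSE)
  }
  if (!identical(dimnames(allele1), dimnames(allele2))) {
    stop("allele matrices must share dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(allele1))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(allele1))) {
    stop("duplicate locus ids", call. = FALSE)
  }
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  if (any(xor(is.na(allele1), is.na(allele2)))) {
    stop("half-missing calls are not allowed: both alleles or neither",
      call. = FALSE)
  }
  ok <- !is.na(allele1)
  if (any(allele1[ok] <= 0L) || any(allele2[ok] <= 0L)) {
    stop("allele sizes must be positive integers (bp)", call. = FALSE)
  }
  # canonical per-cell order
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  structure(
    list(samples = rownames(allele1), loci = colnames(allele1),
      a1 = lo, a2 = hi),
    class = "ssr_table"
  )
}

#' @export
print.ssr_table <- function(x, ...) {
  cat(sprintf("SSR genotype table: %d samples x %d loci\n",
    length(x$samples), length(x$loci)))
  show <- matrix(ifelse(is.na(x$a1), ".",
    paste0(x$a1, "/", x$a2)),
    nrow = length(x$samples),
    dimnames = list(x$samples, x$loci))
  print(show, quote = FALSE, ...)
  invisible(x)
}

#' @export
dim.ssr_table <- function(x) c(length(x$samples), length(x$loci))

#' Extract one genotype call
#'
#' @param tab an [ssr_table].
#' @param sample,locus labels.
#' @return integer vector of length 2 (sorted allele sizes), or `c(NA, NA)`.
#' @export
ssr_call <- function(tab, sample, locus) {
  stopifnot(inherits(tab, "ssr_table"))
  c(tab$a1[sample, locus], tab$a2[sample, locus])
}

is_missing_call <- function(tab) is.na(tab$a1)

#' Read an SSR genotype table from CSV
#'
#' Two dialects are supported. `plain_csv` has one row per sample: a `sample`
#' column then two columns per locus named `<locus>.1` and `<locus>.2`.
#' `genalex` is the codominant GenAlEx-style CSV: a first header row of counts
#' (number of loci, number of samples, then optional population fields), a
#' second header row with `Sample`, `Pop` and one locus name above the first
#' of each allele-column pair, then one data row per sample. In both dialects
#' an empty cell or 0 encodes a missing allele.
#'
#' @param path file path.
#' @param dialect `"plain_csv"` or `"genalex"`.
#' @return an [ssr_table].
#' @export
read_ssr_table <- function(path, dialect = c("plain_csv", "genalex")) {
  dialect <- match.arg(dialect)
  if (dialect == "plain_csv") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (!"sample" %in% names(df)) {
      stop("plain_csv SSR table needs a 'sample' column", call. = FALSE)
    }
    acols <- setdiff(names(df), "sample")
    if (length(acols) %% 2 != 0) {
      stop(sprintf("odd number of allele columns (%d): two per locus required",
        length(acols)), call. = FALSE)
    }
    base <- sub("\\.[12]$", "", acols)
    loci <- unique(base)
    for (lc in loci) {
      want <- paste0(lc, c(".1", ".2"))
      if (!all(want %in% acols)) {
        stop(sprintf("locus '%s' lacks paired columns '%s.1'/'%s.2'",
          lc, lc, lc), call. = FALSE)
      }
    }
    samples <- df$sample
    a1 <- parse_allele_block(df[paste0(loci, ".1")], samples, path)
    a2 <- parse_allele_block(df[paste0(loci, ".2")], samples, path)
    dimnames(a1) <- dimnames(a2) <- list(samples, loci)
    return(ssr_table(a1, a2))
  }
  # genalex dialect
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
    check.names = FALSE)
  if (nrow(raw) < 3) stop("GenAlEx file too short", call. = FALSE)
  n_loci <- suppressWarnings(as.integer(raw[1, 1]))
  n_samples <- suppressWarnings(as.integer(raw[1, 2]))
  if (is.na(n_loci) || is.na(n_samples)) {
    stop("GenAlEx count row must start with <n_loci>,<n_samples>",
      call. = FALSE)
  }
  header <- as.character(raw[2, ])
  need <- 2 + 2 * n_loci
  if (ncol(raw) < need) {
    stop(sprintf("GenAlEx file declares %d loci but has only %d columns",
      n_loci, ncol(raw)), call. = FALSE)
  }
  loci <- header[seq(3, by = 2, length.out = n_loci)]
  if (any(loci == "")) {
    stop("GenAlEx title row must name each locus above its first allele column",
      call. = FALSE)
  }
  data <- raw[-(1:2), , drop = FALSE]
  data <- data[rowSums(data != "") > 0, , drop = FALSE]
  if (nrow(data) != n_samples) {
    stop(sprintf(
      "GenAlEx file declares %d samples but contains %d data rows",
      n_samples, nrow(data)), call. = FALSE)
  }
  samples <- as.character(data[[1]])
  a1 <- parse_allele_block(data[seq(3, by = 2, length.out = n_loci)],
    samples, path)
  a2 <- parse_allele_block(data[seq(4, by = 2, length.out = n_loci)],
    samples, path)
  dimnames(a1) <- dimnames(a2) <- list(samples, loci)
  ssr_table(a1, a2)
}

# character data.frame block -> integer matrix; ""/0/NA -> NA
parse_allele_block <- function(block, samples, path) {
  m <- matrix(NA_integer_, nrow = length(samples), ncol = length(block))
  for (j in seq_along(block)) {
    v <- trimws(as.character(block[[j]]))
    empty <- v == "" | v == "0" | is.na(v)
    num <- suppressWarnings(as.numeric(v))
    bad <- !empty & (is.na(num) | num != round(num) | num < 0)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "non-integer allele size '%s' at row %d, column '%s' of %s",
        v[i], i, names(block)[j], basename(path)), call. = FALSE)
    }
    m[, j] <- ifelse(empty, NA_integer_, as.integer(num))
  }
  m
}

#' Write an SSR genotype table to plain CSV
#'
#' @param tab an [ssr_table].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(tab, path) {
  stopifnot(inherits(tab, "ssr_table"))
  out <- data.frame(sample = tab$samples, stringsAsFactors = FALSE)
  for (lc in tab$loci) {
    out[[paste0(lc, ".1")]] <- ifelse(is.na(tab$a1[, lc]), "", tab$a1[, lc])
    out[[paste0(lc, ".2")]] <- ifelse(is.na(tab$a2[, lc]), "", tab$a2[, lc])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Majority-rule consensus across replicate genotype tables
#'
#' Genotyping replicates (e.g. triplicate PCRs per clone) are merged cell by
#' cell: the call observed in a strict majority of replicates wins; ties and
#' full disagreement yield a missing consensus call. Missing replicate calls
#' do not vote. Every non-unanimous cell is logged.
#'
#' @param tables list of [ssr_table]s with identical samples and loci.
#' @return list with `consensus` (an [ssr_table]) and `report` (a data.frame
#'   with columns `sample`, `locus`, `calls`, `resolution`).
#' @export
consensus_from_replicates <- function(tables) {
  stopifnot(length(tables) >= 1, all(vapply(tables, inherits, TRUE,
    "ssr_table")))
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$samples, ref$samples) || !identical(t$loci, ref$loci)) {
      stop("replicate tables must share identical sample and locus ids",
        call. = FALSE)
    }
  }
  n <- length(ref$samples)
  p <- length(ref$loci)
  a1 <- matrix(NA_integer_, n, p, dimnames = list(ref$samples, ref$loci))
  a2 <- a1
  rep_rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      calls <- vapply(tables, function(t) {
        if (is.na(t$a1[i, j])) NA_character_
        else paste0(t$a1[i, j], "/", t$a2[i, j])
      }, character(1))
      obs <- calls[!is.na(calls)]
      if (length(obs) == 0) next
      tabn <- sort(table(obs), decreasing = TRUE)
      unanimous <- length(tabn) == 1
      majority <- !unanimous && tabn[1] > tabn[2] && tabn[1] * 2 > length(obs)
      if (unanimous || majority) {
        pair <- as.integer(strsplit(names(tabn)[1], "/")[[1]])
        a1[i, j] <- pair[1]
        a2[i, j] <- pair[2]
      }
      if (!unanimous) {
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          sample = ref$samples[i], locus = ref$loci[j],
          calls = paste(calls, collapse = ";"),
          resolution = if (majority) "majority" else "missing",
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(sample = character(), locus = character(),
      calls = character(), resolution = character(),
      stringsAsFactors = FALSE)
  list(consensus = ssr_table(a1, a2), report = report)
}
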