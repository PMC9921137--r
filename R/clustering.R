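#' UPGMA hierarchical clustering
#'
#' Classic unweighted pair-group method with arithmetic mean: repeatedly
#' merge the two clusters with the smallest average inter-cluster distance;
#' after a merge, distances to the new cluster are size-weighted arithmetic
#' means of its parts. The node height of a merge is half the average
#' distance at which it happens (the ultrametric convention: the cophenetic
#' value of two leaves is twice the height of their lowest common ancestor,
#' i.e. on the scale of the input distances). When several pairs attain the
#' minimum, the pair whose smallest leaf labels sort lexicographically first
#' is merged, so identical inputs always give identical trees.
#'
#' @param d a [dist_matrix] with n >= 2 samples.
#' @return an object of class `clone_dendrogram`: list with `labels`,
#'   `merge` (n-1 x 2, hclust convention: negative = leaf, positive = earlier
#'   merge) and `height` (node heights, half the merge distance).
#' @examples
#' m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(dist_matrix(m))
#' @export
upgma <- function(d) {
  stopifnot(inherits(d, "dist_matrix"))
  labels <- dist_labels(d)
  n <- length(labels)
  if (n < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  D <- unclass(d)
  # active clusters: id (hclust convention), size, representative label
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  reps <- labels  # lexicographically smallest member label per cluster
  active <- seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_len(k - 1)) {
      for (jj in (ii + 1):k) {
        dij <- D[active[ii], active[jj]]
        pair_key <- sort(c(reps[active[ii]], reps[active[jj]]))
        if (dij < best_d ||
            (dij == best_d && (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best_d <- dij
          best <- list(i = active[ii], j = active[jj], key = pair_key)
        }
      }
    }
    i <- best$i; j <- best$j
    # child with the lexicographically smaller leaf label goes first, so the
    # Newick string is deterministic too
    merge[step, ] <- if (reps[i] <= reps[j]) c(ids[i], ids[j]) else
      c(ids[j], ids[i])
    height[step] <- best_d / 2
    # size-weighted average linkage update, stored in slot i
    others <- setdiff(active, c(i, j))
    D[i, others] <- D[others, i] <-
      (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
      (sizes[i] + sizes[j])
    sizes[i] <- sizes[i] + sizes[j]
    ids[i] <- step
    reps[i] <- min(reps[i], reps[j])
    active <- setdiff(active, j)
  }
  structure(list(labels = labels, merge = merge, height = height),
    class = "clone_dendrogram")
}

#' @export
print.clone_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, %d merges\n",
    length(x$labels), nrow(x$merge)))
  cat("merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Convert to a stats::hclust object
#'
#' Heights follow the hclust convention (the merge distance, i.e. twice the
#' node height), so [stats::cophenetic] on the result agrees with
#' [cophenetic_matrix].
#'
#' @param x a `clone_dendrogram`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.clone_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = 2 * x$height,
    order = dendrogram_order(x), labels = x$labels,
    method = "average", call = match.call(), dist.method = "user"),
    class = "hclust")
}

# leaf order for plotting: left-to-right traversal
dendrogram_order <- function(x) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(x$merge[node, 1]), rec(x$merge[node, 2]))
  }
  rec(nrow(x$merge))
}

# leaves under each internal node
node_members <- function(x) {
  members <- vector("list", nrow(x$merge))
  for (s in seq_len(nrow(x$merge))) {
    get <- function(id) if (id < 0) -id else members[[id]]
    members[[s]] <- c(get(x$merge[s, 1]), get(x$merge[s, 2]))
  }
  members
}

#' Cophenetic matrix of a dendrogram
#'
#' The cophenetic value of two leaves is twice the node height of their
#' lowest common ancestor — the average distance at which their clusters
#' merged — so it is directly comparable to the input distances. The result
#' is ultrametric.
#'
#' @param tree a `clone_dendrogram`.
#' @return a [dist_matrix].
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "clone_dendrogram"))
  n <- length(tree$labels)
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- node_members(tree)
  for (s in seq_len(nrow(tree$merge))) {
    left <- if (tree$merge[s, 1] < 0) -tree$merge[s, 1] else
      members[[tree$merge[s, 1]]]
    right <- if (tree$merge[s, 2] < 0) -tree$merge[s, 2] else
      members[[tree$merge[s, 2]]]
    cm[left, right] <- cm[right, left] <- 2 * tree$height[s]
  }
  dist_matrix(cm)
}

#' Cophenetic correlation
#'
#' Pearson correlation between the lower triangles (diagonal excluded) of a
#' distance matrix and a cophenetic matrix with the same labels; the
#' standard goodness-of-fit measure for a hierarchical clustering.
#'
#' @param d a [dist_matrix].
#' @param coph a [dist_matrix] (cophenetic values) or a `clone_dendrogram`.
#' @return Pearson r, or `NA` with a warning if either half-matrix is
#'   constant.
#' @export
cophenetic_correlation <- function(d, coph) {
  stopifnot(inherits(d, "dist_matrix"))
  if (inherits(coph, "clone_dendrogram")) coph <- cophenetic_matrix(coph)
  coph <- align_dist(coph, dist_labels(d), "cophenetic matrix")
  v1 <- lower_vec(d)
  v2 <- lower_vec(coph)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("constant distance vector: cophenetic correlation undefined")
    return(NA_real_)
  }
  stats::cor(v1, v2)
}

#' Newick serialization of a dendrogram
#'
#' Branch lengths are parent height minus child height (leaves at height 0),
#' so the path length between two leaves equals their cophenetic value.
#'
#' @param tree a `clone_dendrogram`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string, terminated by ";".
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "clone_dendrogram"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE,
    scientific = FALSE)
  rec <- function(id, parent_h) {
    if (id < 0) {
      return(paste0(tree$labels[-id], ":", fmt(parent_h)))
    }
    h <- tree$height[id]
    paste0("(", rec(tree$merge[id, 1], h), ",",
      rec(tree$merge[id, 2], h), "):", fmt(parent_h - h))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", rec(tree$merge[root, 1], h), ",",
    rec(tree$merge[root, 2], h), ");")
}
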