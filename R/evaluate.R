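#' Cell labeling
#'
#' A partition of cells: dense integer labels starting at 0, one per cell.
#'
#' @param cell_ids character vector of cell identifiers.
#' @param labels integer-like vector of the same length; relabelled to
#'   dense integers starting at 0 (first-appearance order).
#' @return An object of class `"cell_labeling"`.
#' @export
cell_labeling <- function(cell_ids, labels) {
  stopifnot(length(cell_ids) == length(labels))
  labels <- as.integer(factor(labels, levels = unique(labels))) - 1L
  structure(list(cell_ids = as.character(cell_ids), labels = labels),
            class = "cell_labeling")
}

#' @export
print.cell_labeling <- function(x, ...) {
  cat(sprintf("<cell_labeling> %d cells, %d clusters\n",
              length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Cluster cells on a selected gene subset
#'
#' Restricts the (log-scale) matrix to the given genes and clusters the
#' cells with k-means (`nstart = 10`) or agglomerative hierarchical
#' clustering (Euclidean distance, Ward linkage, tree cut at
#' `n_clusters`). Deterministic given `seed`.
#'
#' @param m an `"expr_mat"`.
#' @param genes character vector of gene IDs to cluster on (non-empty).
#' @param n_clusters number of clusters, at least 2.
#' @param seed integer RNG seed (k-means initialization).
#' @param method `"kmeans"` (default) or `"hclust"`.
#' @return A `"cell_labeling"` with labels `0 .. n_clusters - 1`.
#' @export
cluster_cells <- function(m, genes, n_clusters, seed = 1L,
                          method = c("kmeans", "hclust")) {
  stopifnot(inherits(m, "expr_mat"), n_clusters >= 2)
  method <- match.arg(method)
  if (length(genes) == 0L) stop("empty gene list")
  sub <- t(as.matrix(subset_genes(m, genes)$values))  # cells x genes
  L <- nrow(sub)
  if (n_clusters > L) stop("more clusters than cells")
  if (n_clusters == L)
    return(cell_labeling(m$cell_ids, seq_len(L) - 1L))
  labels <- if (method == "kmeans") {
    set.seed(seed)
    stats::kmeans(sub, centers = n_clusters, nstart = 10L,
                  iter.max = 100L)$cluster
  } else {
    stats::cutree(stats::hclust(stats::dist(sub), method = "ward.D2"),
                  k = n_clusters)
  }
  cell_labeling(m$cell_ids, labels)
}

#' Adjusted Rand index between two cell partitions
#'
#' Chance-corrected agreement between two partitions of the same cells
#' (Hubert–Arabie): from the contingency table `n_ij`,
#' `ARI = (sum_ij C(n_ij,2) - E) / ((a + b)/2 - E)` where
#' `a = sum_i C(n_i.,2)`, `b = sum_j C(n_.j,2)` and `E = a b / C(n,2)`.
#' Equals 1 for identical partitions (up to label names) and is near 0 for
#' independent ones.
#'
#' @param a,b `"cell_labeling"` objects over the same cells in the same
#'   order, or plain label vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  la <- if (inherits(a, "cell_labeling")) a$labels else a
  lb <- if (inherits(b, "cell_labeling")) b$labels else b
  if (length(la) != length(lb))
    stop("labelings have different lengths")
  tab <- table(la, lb)
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  E <- ai * bj / choose(sum(tab), 2)
  mx <- (ai + bj) / 2
  if (mx == E) return(if (sij == mx) 1 else 0)  # degenerate partitions
  (sij - E) / (mx - E)
}
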