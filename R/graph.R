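#' Binary expression matrix
#'
#' Low-level constructor for the `{0,1}` matrix over a multimodal gene
#' subset. Each row must contain at least one 0 and one 1: a gene that is
#' entirely above or below its own threshold carries no pairing signal and
#' should have been excluded upstream.
#'
#' @param x a `{0,1}` matrix (base or sparse), genes x cells.
#' @param gene_ids character vector of row identifiers.
#' @param gene_means numeric vector of the per-gene thresholds that
#'   produced `x` (recorded for provenance; `NA` when constructed
#'   directly).
#' @return An object of class `"binary_mat"`.
#' @seealso [binarize()] which builds one from an expression matrix.
#' @export
binary_matrix <- function(x, gene_ids = rownames(x),
                          gene_means = rep(NA_real_, nrow(x))) {
  x <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (length(x@x) && !all(x@x %in% c(0, 1)))
    stop("entries must be 0 or 1")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(x)))
  stopifnot(length(gene_ids) == nrow(x), length(gene_means) == nrow(x))
  rs <- Matrix::rowSums(x)
  bad <- which(rs == 0 | rs == ncol(x))
  if (length(bad))
    stop("gene(s) with all-0 or all-1 rows: ",
         paste(utils::head(gene_ids[bad], 5), collapse = ", "))
  rownames(x) <- gene_ids
  structure(list(x = x, gene_ids = as.character(gene_ids),
                 gene_means = gene_means),
            class = "binary_mat")
}

#' @export
print.binary_mat <- function(x, ...) {
  cat(sprintf("<binary_mat> %d genes x %d cells, %d ones\n",
              nrow(x$x), ncol(x$x), as.integer(sum(x$x))))
  invisible(x)
}

#' Threshold each gene at its own mean expression
#'
#' Discretizes a (multimodal-gene) expression matrix into `{0,1}`: entry
#' `(i, j)` is 1 exactly when gene `i`'s expression in cell `j` is strictly
#' above gene `i`'s mean across all cells. Values equal to the mean map
#' to 0.
#'
#' @param m an `"expr_mat"` with `scale = "log"`, already restricted to
#'   non-constant (multimodal) genes.
#' @return A `"binary_mat"` with the thresholds in `gene_means`.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  if (m$scale != "log")
    stop("binarize expects scale = 'log'")
  v <- m$values
  means <- as.numeric(Matrix::rowMeans(v))
  if (methods::is(v, "sparseMatrix")) {
    # values >= 0 and non-constant rows have mean > 0, so implicit zeros
    # are always below threshold; compare stored entries only
    trip <- Matrix::summary(methods::as(methods::as(v, "generalMatrix"),
                                        "TsparseMatrix"))
    on <- trip$x > means[trip$i]
    x <- Matrix::sparseMatrix(i = trip$i[on], j = trip$j[on], x = 1,
                              dims = dim(v))
  } else {
    x <- (v > means) * 1
  }
  binary_matrix(x, m$gene_ids, means)
}

new_pair_counts <- function(counts, gene_ids,
                            kind = c("cooccurrence", "mutual_exclusive")) {
  kind <- match.arg(kind)
  dimnames(counts) <- list(gene_ids, gene_ids)
  structure(list(counts = counts, gene_ids = gene_ids, kind = kind),
            class = "pair_counts")
}

#' Pairwise co-occurrence counts S = X X'
#'
#' `S[i, j]` is the number of cells in which genes `i` and `j` are both
#' expressed (both 1 in the binary matrix). The diagonal holds each gene's
#' expressing-cell count.
#'
#' @param x a `"binary_mat"`.
#' @return A `"pair_counts"` object with `kind = "cooccurrence"`.
#' @export
cooccurrence <- function(x) {
  stopifnot(inherits(x, "binary_mat"))
  S <- as.matrix(Matrix::tcrossprod(x$x))
  storage.mode(S) <- "integer"
  new_pair_counts(S, x$gene_ids, "cooccurrence")
}

#' Pairwise mutual-exclusivity counts M = (1 - X) X'
#'
#' `M[i, j]` is the number of cells in which gene `i` is off while gene `j`
#' is on (asymmetric). Computed from the co-occurrence product via the
#' exact identity `M[i, j] = S[j, j] - S[i, j]`, so the dense complement
#' `1 - X` is never materialized.
#'
#' @param x a `"binary_mat"`.
#' @return A `"pair_counts"` object with `kind = "mutual_exclusive"` and a
#'   zero diagonal.
#' @export
mutual_exclusive <- function(x) {
  stopifnot(inherits(x, "binary_mat"))
  S <- as.matrix(Matrix::tcrossprod(x$x))
  M <- matrix(diag(S), nrow(S), ncol(S), byrow = TRUE) - S
  storage.mode(M) <- "integer"
  new_pair_counts(M, x$gene_ids, "mutual_exclusive")
}

#' Directed k-nearest-neighbour gene graph
#'
#' For every gene `A`, candidate neighbours are the genes `B != A` whose
#' pair count with `A` is at least `n`; edges `A -> B` go to the `k`
#' candidates with the largest counts (ties at the cut broken by ascending
#' gene index, so the graph is deterministic). If fewer than `k` candidates
#' pass the threshold, all are kept.
#'
#' @param counts a `"pair_counts"` object ([cooccurrence()] or
#'   [mutual_exclusive()]).
#' @param k maximum out-degree, `k >= 1`.
#' @param n minimum supporting cell count per edge, `n >= 1`.
#' @return An object of class `"neighbor_graph"` with an `edges`
#'   data.frame (`from`, `to`, `weight`; integer gene indices).
#' @export
neighbor_graph <- function(counts, k, n) {
  stopifnot(inherits(counts, "pair_counts"), k >= 1, n >= 1)
  C <- counts$counts
  N <- nrow(C)
  from <- to <- wt <- vector("list", N)
  for (a in seq_len(N)) {
    w <- C[a, ]
    cand <- which(w >= n)
    cand <- cand[cand != a]
    if (!length(cand)) next
    cand <- cand[order(-w[cand], cand)]
    cand <- cand[seq_len(min(k, length(cand)))]
    from[[a]] <- rep.int(a, length(cand))
    to[[a]] <- cand
    wt[[a]] <- w[cand]
  }
  edges <- data.frame(from = unlist(from) %||% integer(0),
                      to = unlist(to) %||% integer(0),
                      weight = as.integer(unlist(wt) %||% integer(0)))
  structure(list(kind = counts$kind, k = as.integer(k), n = as.integer(n),
                 edges = edges, gene_ids = counts$gene_ids),
            class = "neighbor_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> kind=%s k=%d n=%d: %d genes, %d edges\n",
              x$kind, x$k, x$n, length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

adjacency <- function(g) {
  N <- length(g$gene_ids)
  A <- matrix(FALSE, N, N)
  if (nrow(g$edges)) A[cbind(g$edges$from, g$edges$to)] <- TRUE
  A
}

#' Reciprocally connected gene pairs
#'
#' A pair `{A, B}` qualifies when `A -> B` and `B -> A` are both edges of
#' the co-occurrence graph, or both edges of the mutual-exclusivity graph.
#' These bidirectional pairs are the marker-defining units: genes in at
#' least one such pair are selected as markers.
#'
#' @param g_con co-occurrence `"neighbor_graph"`.
#' @param g_mex mutual-exclusivity `"neighbor_graph"` over the same genes
#'   (or `NULL` to use only one graph).
#' @return A data.frame with integer columns `a`, `b` (`a < b`), character
#'   `gene_a`, `gene_b`, and `kind` in `"cooccurrence"`,
#'   `"mutual_exclusive"` or `"both"`.
#' @export
reciprocal_pairs <- function(g_con, g_mex = NULL) {
  stopifnot(inherits(g_con, "neighbor_graph"))
  pair_set <- function(g) {
    A <- adjacency(g)
    R <- A & t(A)
    which(R & upper.tri(R), arr.ind = TRUE)
  }
  pc <- pair_set(g_con)
  pm <- if (is.null(g_mex)) pc[0, , drop = FALSE] else {
    stopifnot(identical(g_con$gene_ids, g_mex$gene_ids))
    pair_set(g_mex)
  }
  key_c <- paste(pc[, 1], pc[, 2])
  key_m <- paste(pm[, 1], pm[, 2])
  keys <- union(key_c, key_m)
  if (!length(keys))
    return(data.frame(a = integer(0), b = integer(0),
                      gene_a = character(0), gene_b = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  ab <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]; keys <- keys[ord]
  kind <- ifelse(keys %in% key_c & keys %in% key_m, "both",
                 ifelse(keys %in% key_c, "cooccurrence", "mutual_exclusive"))
  data.frame(a = a, b = b,
             gene_a = g_con$gene_ids[a], gene_b = g_con$gene_ids[b],
             kind = kind, stringsAsFactors = FALSE)
}

# graph stage shared by select_markers() and sweep_markers(): binary matrix
# in, marker indices + pair provenance out
markers_from_binary <- function(bin, k, n) {
  S <- cooccurrence(bin)
  M <- mutual_exclusive(bin)
  g_con <- neighbor_graph(S, k, n)
  g_mex <- neighbor_graph(M, k, n)
  pairs <- reciprocal_pairs(g_con, g_mex)
  idx <- sort(unique(c(pairs$a, pairs$b)))
  list(marker_idx = idx, pairs = pairs, g_con = g_con, g_mex = g_mex)
}
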