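#' Select marker genes from a single-cell expression matrix
#'
#' The package's main fitting function. Marker genes are selected in two
#' annotation-free stages:
#'
#' 1. *Modality filter*: each gene's per-cell expression density is
#'    estimated with a Gaussian kernel (bandwidth `h`); only genes whose
#'    density has two or more peaks — the signature of a gene expressed in
#'    some subpopulations but not others — are retained.
#' 2. *Pairing filter*: the multimodal submatrix is binarized at each
#'    gene's mean, pairwise co-occurrence (`S = X X'`) and
#'    mutual-exclusivity (`M = (1 - X) X'`) cell counts are computed, and
#'    two directed k-nearest-neighbour graphs are built (edges require at
#'    least `n` supporting cells; at most `k` strongest neighbours per
#'    gene). Genes in at least one reciprocally connected pair, in either
#'    graph, are the markers.
#'
#' @param x an [expression_matrix()] with `scale = "log"` (use
#'   [log_normalize()] on raw counts first).
#' @param k neighbourhood size of the gene graphs, default 300.
#' @param n minimum number of supporting cells per graph edge, default 30.
#' @param h fixed kernel bandwidth; `NULL` picks the platform default
#'   (0.3 for `smart_seq`/`unknown`, 0.05 for `droplet`).
#' @param h_mode `"fixed"` (default) or `"per_gene"` (Silverman rule).
#' @param grid_size minimum density grid resolution, see
#'   [multimodal_genes()].
#' @return An object of class `"marker_selection"`; see Details.
#'
#' @details The returned object has components
#' \describe{
#'   \item{markers}{character vector of selected gene IDs, in input gene
#'     order.}
#'   \item{provenance}{data.frame per marker: `gene_id`, `peak_count`,
#'     `n_partners`, `partner_ids`, `pair_kinds`.}
#'   \item{pairs}{data.frame of reciprocal gene pairs with their kind.}
#'   \item{profiles}{density profiles of all multimodal genes.}
#'   \item{counts}{genes surviving each stage (input, multimodal,
#'     marker).}
#'   \item{params}{the resolved `k`, `n`, `h`, `h_mode`.}
#' }
#' `print()`, `summary()` and `plot()` methods are provided, plus
#' [markers()] and [write_markers()].
#' @export
#' @examples
#' sim <- simulate_cells(n_cells = 120, n_genes = 60, n_marker_genes = 10,
#'                       seed = 1)
#' fit <- select_markers(sim$expression, k = 50, n = 10)
#' fit
select_markers <- function(x, k = 300, n = 30, h = NULL,
                           h_mode = c("fixed", "per_gene"),
                           grid_size = 512L) {
  stopifnot(inherits(x, "expr_mat"), k >= 1, n >= 1)
  h_mode <- match.arg(h_mode)
  if (is.null(h)) h <- default_bandwidth(x$platform)
  cl <- match.call()
  profiles <- multimodal_genes(x, h_mode = h_mode, h_fixed = h,
                               grid_size = grid_size)
  empty <- function() {
    structure(list(markers = character(0),
                   provenance = data.frame(gene_id = character(0),
                                           peak_count = integer(0),
                                           n_partners = integer(0),
                                           partner_ids = character(0),
                                           pair_kinds = character(0),
                                           stringsAsFactors = FALSE),
                   pairs = reciprocal_pairs(neighbor_graph(
                     new_pair_counts(matrix(0L, 0, 0), character(0),
                                     "cooccurrence"), k, n)),
                   profiles = profiles,
                   counts = c(input = nrow(x$values),
                              multimodal = length(profiles), marker = 0L),
                   params = list(k = k, n = n, h = h, h_mode = h_mode),
                   call = cl),
              class = "marker_selection")
  }
  if (length(profiles) < 2L) {
    warning("fewer than 2 multimodal genes; no markers can be selected")
    return(empty())
  }
  sub <- subset_genes(x, names(profiles))
  bin <- binarize(sub)
  res <- markers_from_binary(bin, k, n)
  marker_ids <- bin$gene_ids[res$marker_idx]
  prov <- do.call(rbind, lapply(res$marker_idx, function(i) {
    hit <- res$pairs$a == i | res$pairs$b == i
    partners <- ifelse(res$pairs$a[hit] == i,
                       res$pairs$gene_b[hit], res$pairs$gene_a[hit])
    data.frame(gene_id = bin$gene_ids[i],
               peak_count = profiles[[bin$gene_ids[i]]]$peak_count,
               n_partners = sum(hit),
               partner_ids = paste(partners, collapse = ","),
               pair_kinds = paste(res$pairs$kind[hit], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(prov))
    prov <- data.frame(gene_id = character(0), peak_count = integer(0),
                       n_partners = integer(0), partner_ids = character(0),
                       pair_kinds = character(0), stringsAsFactors = FALSE)
  structure(list(markers = marker_ids,
                 provenance = prov,
                 pairs = res$pairs,
                 profiles = profiles,
                 graphs = list(cooccurrence = res$g_con,
                               mutual_exclusive = res$g_mex),
                 counts = c(input = nrow(x$values),
                            multimodal = length(profiles),
                            marker = length(marker_ids)),
                 params = list(k = k, n = n, h = h, h_mode = h_mode),
                 call = cl),
            class = "marker_selection")
}

#' Extract selected marker gene IDs
#'
#' @param object a `"marker_selection"` fit.
#' @param ... unused.
#' @return Character vector of marker gene IDs.
#' @export
markers <- function(object, ...) UseMethod("markers")

#' @export
markers.marker_selection <- function(object, ...) object$markers

#' @export
print.marker_selection <- function(x, ...) {
  cat("Marker selection by multimodality and reciprocal gene pairing\n")
  cat(sprintf("  parameters: k = %d, n = %d, h = %s (%s)\n",
              x$params$k, x$params$n, format(x$params$h), x$params$h_mode))
  cat(sprintf("  genes: %d input -> %d multimodal -> %d markers\n",
              x$counts["input"], x$counts["multimodal"], x$counts["marker"]))
  if (length(x$markers))
    cat("  markers: ", paste(utils::head(x$markers, 8), collapse = ", "),
        if (length(x$markers) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.marker_selection <- function(object, ...) {
  kinds <- table(factor(object$pairs$kind,
                        levels = c("cooccurrence", "mutual_exclusive",
                                   "both")))
  structure(list(counts = object$counts, params = object$params,
                 n_pairs = nrow(object$pairs), pair_kinds = kinds,
                 provenance = object$provenance),
            class = "summary.marker_selection")
}

#' @export
print.summary.marker_selection <- function(x, ...) {
  cat(sprintf("genes: %d input, %d multimodal, %d selected as markers\n",
              x$counts["input"], x$counts["multimodal"], x$counts["marker"]))
  cat(sprintf("reciprocal pairs: %d (cooccurrence %d, mutual-exclusive %d, both %d)\n",
              x$n_pairs, x$pair_kinds[1], x$pair_kinds[2], x$pair_kinds[3]))
  cat(sprintf("parameters: k = %d, n = %d, h = %s (%s)\n",
              x$params$k, x$params$n, format(x$params$h), x$params$h_mode))
  if (nrow(x$provenance)) {
    cat("top markers by pair degree:\n")
    ord <- order(-x$provenance$n_partners)
    print(utils::head(x$provenance[ord, c("gene_id", "peak_count",
                                          "n_partners")], 10),
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot expression densities of selected markers
#'
#' Draws the kernel density estimates (with detected peak positions) for
#' up to `max_genes` selected markers.
#'
#' @param x a `"marker_selection"` fit.
#' @param max_genes number of panels, default 9.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.marker_selection <- function(x, max_genes = 9, ...) {
  ids <- utils::head(x$markers, max_genes)
  if (!length(ids)) {
    warning("no markers to plot")
    return(invisible(x))
  }
  nc <- ceiling(sqrt(length(ids)))
  nr <- ceiling(length(ids) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (id in ids) {
    p <- x$profiles[[id]]
    graphics::plot(p$grid, p$density, type = "l", xlab = "", ylab = "",
                   main = sprintf("%s (T = %d)", id, p$peak_count), ...)
    graphics::abline(v = p$peak_positions, lty = 3, col = "red3")
  }
  invisible(x)
}

#' Write marker list and provenance files
#'
#' Writes `<prefix>.markers.txt` (one gene ID per line) and
#' `<prefix>.provenance.tsv` (`gene_id`, `peak_count`, `n_partners`,
#' `partner_ids`, `pair_kinds`). With `edges = TRUE`, also
#' `<prefix>.edges.tsv` (`source`, `target`, `weight`, `graph_kind`).
#'
#' @param object a `"marker_selection"` fit.
#' @param prefix output path prefix.
#' @param edges also export the two graphs' edge lists, default `FALSE`.
#' @return The paths written, invisibly.
#' @export
write_markers <- function(object, prefix, edges = FALSE) {
  stopifnot(inherits(object, "marker_selection"))
  paths <- c(markers = paste0(prefix, ".markers.txt"),
             provenance = paste0(prefix, ".provenance.tsv"))
  writeLines(object$markers, paths["markers"])
  utils::write.table(object$provenance, paths["provenance"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (edges) {
    paths <- c(paths, edges = paste0(prefix, ".edges.tsv"))
    el <- do.call(rbind, lapply(object$graphs, function(g)
      data.frame(source = g$gene_ids[g$edges$from],
                 target = g$gene_ids[g$edges$to],
                 weight = g$edges$weight, graph_kind = g$kind,
                 stringsAsFactors = FALSE)))
    if (is.null(el))
      el <- data.frame(source = character(0), target = character(0),
                       weight = integer(0), graph_kind = character(0))
    utils::write.table(el, paths["edges"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
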