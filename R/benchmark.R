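#' Marker counts over a grid of graph parameters
#'
#' Runs the expensive pipeline stages once (modality filter, binarization,
#' pair counts) and then rebuilds the two gene graphs for every `(k, n)`
#' combination, reporting the marker count per cell of the grid —
#' the robustness-style exploration used to choose defaults. If truth
#' labels are supplied, a k-means adjusted Rand index on the selected
#' markers is added per cell.
#'
#' @param m an `"expr_mat"` with `scale = "log"`.
#' @param k_values,n_values integer vectors of graph parameters.
#' @param h,h_mode,grid_size passed to [multimodal_genes()].
#' @param labels optional `"cell_labeling"` ground truth; when given, the
#'   report gains an `ari` column (k-means with `n_clusters` clusters).
#' @param n_clusters clusters for the optional ARI, default the number of
#'   distinct labels.
#' @param seed k-means seed for the optional ARI.
#' @return A data.frame with one row per `(k, n)`: `k`, `n`, `n_markers`
#'   and optionally `ari`.
#' @export
sweep_markers <- function(m, k_values, n_values, h = NULL,
                          h_mode = "fixed", grid_size = 512L,
                          labels = NULL, n_clusters = NULL, seed = 1L) {
  stopifnot(inherits(m, "expr_mat"), all(k_values >= 1), all(n_values >= 1))
  if (is.null(h)) h <- default_bandwidth(m$platform)
  profiles <- multimodal_genes(m, h_mode = h_mode, h_fixed = h,
                               grid_size = grid_size)
  grid <- expand.grid(k = as.integer(k_values), n = as.integer(n_values))
  if (length(profiles) < 2L) {
    grid$n_markers <- 0L
    return(grid)
  }
  bin <- binarize(subset_genes(m, names(profiles)))
  S <- cooccurrence(bin)
  M <- mutual_exclusive(bin)
  if (!is.null(labels) && is.null(n_clusters))
    n_clusters <- length(unique(labels$labels))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g_con <- neighbor_graph(S, grid$k[r], grid$n[r])
    g_mex <- neighbor_graph(M, grid$k[r], grid$n[r])
    pairs <- reciprocal_pairs(g_con, g_mex)
    ids <- bin$gene_ids[sort(unique(c(pairs$a, pairs$b)))]
    out <- data.frame(k = grid$k[r], n = grid$n[r],
                      n_markers = length(ids))
    if (!is.null(labels))
      out$ari <- if (length(ids) == 0) NA_real_ else
        adjusted_rand_index(
          cluster_cells(m, ids, n_clusters, seed = seed), labels)
    out
  })
  do.call(rbind, rows)
}

#' Compare marker selectors on simulated data
#'
#' For each seed: simulate a mixed-population matrix, select markers with
#' the graph-based method, draw equal-size gene sets with the two baseline
#' selectors (highest mean expression; highest variance), cluster the
#' cells on each gene set and score the clustering against the true
#' populations with the adjusted Rand index.
#'
#' @param seeds integer vector of simulation seeds.
#' @param k,n,h selection parameters, defaults `k = 300`, `n = 30`,
#'   platform-default `h`.
#' @param clustering_methods subset of `c("kmeans", "hclust")`.
#' @param variable_method baseline variability ranking, see
#'   [top_variable()].
#' @param ... simulation parameters forwarded to [simulate_cells()]
#'   (everything except `seed`).
#' @return A data.frame with one row per selector x clustering method x
#'   seed: `selector`, `n_genes`, `clustering_method`, `seed`, `ari`.
#'   Selectors are `"marker_graph"`, `"highest_expressed"`,
#'   `"highest_variable"`.
#' @export
benchmark_selectors <- function(seeds, k = 300, n = 30, h = NULL,
                                clustering_methods = "kmeans",
                                variable_method = "variance", ...) {
  stopifnot(length(seeds) >= 1)
  clustering_methods <- match.arg(clustering_methods,
                                  c("kmeans", "hclust"),
                                  several.ok = TRUE)
  rows <- list()
  for (s in seeds) {
    sim <- simulate_cells(..., seed = s)
    fit <- select_markers(sim$expression, k = k, n = n, h = h)
    size <- length(fit$markers)
    sets <- list(marker_graph = fit$markers)
    if (size >= 1) {
      sets$highest_expressed <- top_expressed(sim$expression, size)$gene_ids
      sets$highest_variable <- top_variable(sim$expression, size,
                                            method = variable_method)$gene_ids
    }
    ncl <- sim$config$n_populations
    for (sel in names(sets)) for (cm in clustering_methods) {
      ari <- if (length(sets[[sel]]) == 0) NA_real_ else
        adjusted_rand_index(
          cluster_cells(sim$expression, sets[[sel]], ncl,
                        seed = s, method = cm),
          sim$labels)
      rows[[length(rows) + 1L]] <-
        data.frame(selector = sel, n_genes = size,
                   clustering_method = cm, seed = s, ari = ari,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Precision and recall of planted-marker recovery
#'
#' @param selected character vector of selected gene IDs.
#' @param truth character vector of true planted marker IDs.
#' @return Named numeric vector `c(precision, recall)`; precision is `NA`
#'   when nothing was selected.
#' @export
marker_recovery <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  c(precision = if (length(selected) == 0) NA_real_
    else tp / length(selected),
    recall = tp / length(truth))
}
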