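# Reference-condition simulation runs, computed lazily and cached for the
# duration of the test session so the recovery and comparison checks can
# share them.

.ref_cache <- new.env(parent = emptyenv())

reference_seeds <- function() 101:110

# one full pipeline run at the reference condition: simulate, select
# markers, draw equal-size baseline sets, cluster each with k-means
reference_run <- function(seed) {
  key <- paste0("seed", seed)
  if (!is.null(.ref_cache[[key]])) return(.ref_cache[[key]])
  sim <- simulate_cells(seed = seed)   # reference defaults
  fit <- select_markers(sim$expression)
  size <- length(markers(fit))
  ari <- function(ids) if (!length(ids)) NA_real_ else
    adjusted_rand_index(
      cluster_cells(sim$expression, ids, sim$config$n_populations,
                    seed = seed),
      sim$labels)
  heg <- if (size) top_expressed(sim$expression, size)$gene_ids else character(0)
  hvg <- if (size) top_variable(sim$expression, size)$gene_ids else character(0)
  res <- list(
    recovery = marker_recovery(markers(fit), sim$markers),
    n_markers = size,
    ari = c(marker_graph = ari(markers(fit)),
            highest_expressed = ari(heg),
            highest_variable = ari(hvg)))
  .ref_cache[[key]] <- res
  res
}
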