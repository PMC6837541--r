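#' Simulate a mixed-population expression matrix with planted markers
#'
#' Generates a log-scale gene-by-cell matrix containing two kinds of
#' genes:
#' \describe{
#'   \item{marker genes}{each is assigned one "on" population
#'     (round-robin across populations); its cells draw
#'     `Normal(base_mean + marker_shift, base_sd)` when the cell belongs
#'     to that population and `Normal(base_mean, base_sd)` otherwise.
#'     Markers sharing an on-population are co-occurring; markers of
#'     different populations are mutually exclusive, so both graph kinds
#'     are exercised.}
#'   \item{background genes}{all cells draw `Normal(base_mean, base_sd)`.}
#' }
#' Draws are clamped at 0 (expression is non-negative), and each entry is
#' then independently zeroed with probability `dropout_rate`, emulating
#' the zero inflation of real single-cell data. With the default
#' `base_mean = 0`, background genes are half-clamped Gaussians with a
#' single mode at 0, so dropout does not fabricate bimodality.
#'
#' Defaults are the package's reference condition: 2 equal populations,
#' 500 cells, 1000 genes of which 40 are markers, an on/off separation of
#' 4 log2 units with spread 0.5, and 10% dropout.
#'
#' @param n_cells number of cells, default 500.
#' @param n_genes number of genes, default 1000.
#' @param n_populations number of populations, at least 2, default 2.
#' @param population_fractions simplex vector of length `n_populations`;
#'   default equal fractions.
#' @param n_marker_genes number of planted markers, default 40.
#' @param marker_shift on/off mean separation in log2 units, default 4.
#' @param base_mean baseline mean, default 0.
#' @param base_sd baseline standard deviation, default 0.5.
#' @param dropout_rate independent zeroing probability in `[0, 1]`,
#'   default 0.1.
#' @param seed integer RNG seed; output is bit-identical for equal seeds.
#' @return A list of class `"sim_expression"`:
#'   `expression` (an `"expr_mat"`, `scale = "log"`),
#'   `labels` (a `"cell_labeling"` with the true populations),
#'   `markers` (character vector of true marker gene IDs),
#'   `marker_populations` (integer on-population per marker, 0-based),
#'   `config` (the resolved parameters).
#' @export
simulate_cells <- function(n_cells = 500L, n_genes = 1000L,
                           n_populations = 2L,
                           population_fractions = NULL,
                           n_marker_genes = 40L, marker_shift = 4,
                           base_mean = 0, base_sd = 0.5,
                           dropout_rate = 0.1, seed = 1L) {
  if (n_populations < 2L) stop("need at least 2 populations")
  if (is.null(population_fractions))
    population_fractions <- rep(1 / n_populations, n_populations)
  if (length(population_fractions) != n_populations)
    stop("population_fractions length must equal n_populations")
  if (abs(sum(population_fractions) - 1) > 1e-9)
    stop("population_fractions must sum to 1")
  if (n_marker_genes > n_genes)
    stop("n_marker_genes cannot exceed n_genes")
  stopifnot(n_cells >= 2, marker_shift >= 0, base_sd > 0,
            dropout_rate >= 0, dropout_rate <= 1)
  set.seed(as.integer(seed))
  sizes <- diff(round(cumsum(c(0, population_fractions)) * n_cells))
  labels <- rep.int(seq_len(n_populations) - 1L, sizes)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  marker_pop <- (seq_len(n_marker_genes) - 1L) %% n_populations
  vals <- matrix(stats::rnorm(n_genes * n_cells, base_mean, base_sd),
                 n_genes, n_cells)
  for (g in seq_len(n_marker_genes))
    vals[g, labels == marker_pop[g]] <-
      vals[g, labels == marker_pop[g]] + marker_shift
  vals <- pmax(vals, 0)
  if (dropout_rate > 0)
    vals[stats::runif(length(vals)) < dropout_rate] <- 0
  structure(list(
    expression = expression_matrix(vals, gene_ids, cell_ids,
                                   scale = "log", platform = "unknown"),
    labels = cell_labeling(cell_ids, labels),
    markers = gene_ids[seq_len(n_marker_genes)],
    marker_populations = marker_pop,
    config = list(n_cells = n_cells, n_genes = n_genes,
                  n_populations = n_populations,
                  population_fractions = population_fractions,
                  n_marker_genes = n_marker_genes,
                  marker_shift = marker_shift, base_mean = base_mean,
                  base_sd = base_sd, dropout_rate = dropout_rate,
                  seed = as.integer(seed))),
    class = "sim_expression")
}

#' @export
print.sim_expression <- function(x, ...) {
  cat(sprintf(paste0("<sim_expression> %d genes x %d cells, %d populations, ",
                     "%d planted markers (shift %.3g, dropout %.3g, seed %d)\n"),
              x$config$n_genes, x$config$n_cells, x$config$n_populations,
              x$config$n_marker_genes, x$config$marker_shift,
              x$config$dropout_rate, x$config$seed))
  invisible(x)
}

#' Write a simulation as fixture files
#'
#' Writes the matrix in both supported input formats (dense TSV and a
#' matrix-market triplet) plus the ground truth: `markers.txt` (one true
#' marker per line) and `labels.tsv` (`cell_id`, `label`).
#'
#' @param sim a `"sim_expression"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_expression"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_expression_10x(sim$expression, file.path(dir, "mtx"))
  writeLines(sim$markers, file.path(dir, "markers.txt"))
  utils::write.table(
    data.frame(cell_id = sim$labels$cell_ids, label = sim$labels$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
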