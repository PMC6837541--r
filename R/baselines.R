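#' Ranked gene list
#'
#' Container for the two canonical baseline selectors: genes ordered by a
#' per-gene score, scores non-increasing, ties broken by input gene index.
#'
#' @name ranked_genes
#' @keywords internal
new_ranked_genes <- function(gene_ids, scores, criterion) {
  structure(list(gene_ids = gene_ids, scores = scores,
                 criterion = criterion),
            class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, ...) {
  cat(sprintf("<ranked_genes> %d genes by %s; top: %s\n",
              length(x$gene_ids), x$criterion,
              paste(utils::head(x$gene_ids, 5), collapse = ", ")))
  invisible(x)
}

#' Highest-expressed gene baseline
#'
#' Ranks genes by mean expression across cells and keeps the top `count`.
#'
#' @param m an `"expr_mat"`.
#' @param count number of genes to return, `count <= N`.
#' @return A `"ranked_genes"` object with `criterion = "mean_expression"`.
#' @export
top_expressed <- function(m, count) {
  stopifnot(inherits(m, "expr_mat"), count >= 1,
            count <= nrow(m$values))
  mu <- as.numeric(Matrix::rowMeans(m$values))
  ord <- order(-mu, seq_along(mu))[seq_len(count)]
  new_ranked_genes(m$gene_ids[ord], mu[ord], "mean_expression")
}

#' Highest-variable gene baseline
#'
#' Ranks genes either by raw per-gene sample variance, or by a mean-binned
#' standardized dispersion: dispersion = variance / mean, z-scored within
#' 20 equal-frequency bins of gene mean expression, which removes the
#' mean-variance trend before ranking (the usual highly-variable-gene
#' recipe).
#'
#' @param m an `"expr_mat"`.
#' @param count number of genes to return, `count <= N`.
#' @param method `"variance"` (default) or `"dispersion_binned"`.
#' @param n_bins bins for the dispersion method, default 20.
#' @return A `"ranked_genes"` object with `criterion = "dispersion"`.
#' @export
top_variable <- function(m, count,
                         method = c("variance", "dispersion_binned"),
                         n_bins = 20L) {
  stopifnot(inherits(m, "expr_mat"), count >= 1,
            count <= nrow(m$values))
  method <- match.arg(method)
  v <- m$values
  L <- ncol(v)
  mu <- as.numeric(Matrix::rowMeans(v))
  vr <- (as.numeric(Matrix::rowSums(v * v)) - L * mu^2) / (L - 1)
  vr <- pmax(vr, 0)  # clamp tiny negative rounding
  score <- if (method == "variance") vr else {
    disp <- vr / pmax(mu, .Machine$double.eps)
    bins <- as.integer(cut(rank(mu, ties.method = "first"),
                           breaks = n_bins, labels = FALSE))
    z <- disp
    for (b in unique(bins)) {
      i <- bins == b
      s <- stats::sd(disp[i])
      z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
    }
    z
  }
  ord <- order(-score, seq_along(score))[seq_len(count)]
  new_ranked_genes(m$gene_ids[ord], score[ord],
                   if (method == "variance") "dispersion" else "dispersion")
}

#' Write a ranked baseline gene list
#'
#' One gene ID per line, preceded by a `# criterion:` comment header, the
#' same plain-text layout as the marker list.
#'
#' @param ranked a `"ranked_genes"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranked <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_genes"))
  writeLines(c(paste0("# criterion: ", ranked$criterion), ranked$gene_ids),
             path)
  invisible(path)
}
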