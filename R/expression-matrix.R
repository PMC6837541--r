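#' Gene-by-cell expression matrix
#'
#' Construct the container used throughout the package: a non-negative
#' `N x L` matrix of expression values (genes as rows, cells as columns)
#' together with unique gene and cell identifiers, a scale tag and a
#' platform tag. The scale tag guards against double log-transformation and
#' enforces that density estimation and binarization always operate on a
#' compressed, log-like scale.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, genes x cells,
#'   all entries non-negative and non-missing.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param scale one of `"raw_counts"`, `"normalized"`, `"log"`; what the
#'   values represent.
#' @param platform one of `"unknown"`, `"smart_seq"`, `"droplet"`; used to
#'   pick the default kernel bandwidth (0.3 for full-transcript plate data,
#'   0.05 for 3' droplet data).
#'
#' @return An object of class `"expr_mat"`: a list with elements `values`,
#'   `gene_ids`, `cell_ids`, `scale`, `platform`.
#' @seealso [read_expression()], [read_expression_10x()], [log_normalize()]
#' @export
#' @examples
#' m <- expression_matrix(matrix(0:5, 2, 3), c("g1", "g2"),
#'                        c("c1", "c2", "c3"), scale = "log")
#' dim(m)
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              scale = c("raw_counts", "normalized", "log"),
                              platform = c("unknown", "smart_seq", "droplet")) {
  scale <- match.arg(scale)
  platform <- match.arg(platform)
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("`values` must be a matrix (base or Matrix package)")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (or set dimnames on `values`)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != number of rows")
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) != number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell IDs: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyNA(values))
    stop("missing values are not allowed")
  if (nrow(values) >= 1 && ncol(values) >= 1 && min(values) < 0)
    stop("negative expression values are not allowed")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 scale = scale, platform = platform),
            class = "expr_mat")
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d cells [scale=%s, platform=%s]\n",
              nrow(x$values), ncol(x$values), x$scale, x$platform))
  invisible(x)
}

#' Restrict an expression matrix to a subset of genes
#'
#' @param m an [expression_matrix()] object.
#' @param genes character vector of gene IDs (order preserved) or an
#'   integer/logical row index.
#' @return An `"expr_mat"` restricted to the requested genes.
#' @export
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "expr_mat"))
  if (is.character(genes)) {
    miss <- setdiff(genes, m$gene_ids)
    if (length(miss))
      stop("unknown gene IDs: ", paste(utils::head(miss, 5), collapse = ", "))
    idx <- match(genes, m$gene_ids)
  } else {
    idx <- seq_along(m$gene_ids)[genes]
  }
  expression_matrix(m$values[idx, , drop = FALSE], m$gene_ids[idx],
                    m$cell_ids, scale = m$scale, platform = m$platform)
}

#' Read a dense delimited expression table
#'
#' Reads a genes-as-rows (default) or cells-as-rows delimited text table.
#' The first row holds cell IDs (an optional leading corner label is
#' tolerated) and the first column holds gene IDs.
#'
#' @param path file path.
#' @param delimiter single field-separator character, default tab.
#' @param genes_as_rows if `FALSE` the file is transposed on read so the
#'   returned matrix is always genes x cells.
#' @param scale,platform tags for the returned matrix, see
#'   [expression_matrix()].
#' @return An `"expr_mat"` object, genes x cells.
#' @export
read_expression <- function(path, delimiter = "\t", genes_as_rows = TRUE,
                            scale = "raw_counts", platform = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("no data rows in ", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  header <- parts[[1L]]
  body <- parts[-1L]
  nf <- length(body[[1L]])
  if (nf < 2L) stop("need at least one ID column and one value column")
  bad <- which(vapply(body, length, 1L) != nf)
  if (length(bad))
    stop("ragged table: row ", bad[1L] + 1L, " has a different field count")
  if (length(header) == nf) {
    col_ids <- header[-1L]            # leading corner label present
  } else if (length(header) == nf - 1L) {
    col_ids <- header                 # bare ID header
  } else {
    stop("header field count does not match data rows")
  }
  row_ids <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_real_, length(body), nf - 1L)
  for (i in seq_along(body)) {
    x <- suppressWarnings(as.numeric(body[[i]][-1L]))
    j <- which(is.na(x))
    if (length(j))
      stop(sprintf("non-numeric value '%s' for row '%s', column '%s'",
                   body[[i]][j[1L] + 1L], row_ids[i], col_ids[j[1L]]))
    vals[i, ] <- x
  }
  if (genes_as_rows) {
    expression_matrix(vals, row_ids, col_ids, scale = scale,
                      platform = platform)
  } else {
    expression_matrix(t(vals), col_ids, row_ids, scale = scale,
                      platform = platform)
  }
}

#' Write a dense delimited expression table
#'
#' Emits the same dialect [read_expression()] accepts: a header line
#' `gene_id<delim>cell IDs...` followed by one row per gene. Values are
#' written with 15 significant digits so a write/read round trip preserves
#' them to well below 1e-9.
#'
#' @param m an `"expr_mat"` object.
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  stopifnot(inherits(m, "expr_mat"))
  v <- as.matrix(m$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", m$cell_ids), collapse = delimiter), con)
  body <- apply(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                1L, paste, collapse = delimiter)
  writeLines(paste(m$gene_ids, body, sep = delimiter), con)
  invisible(path)
}

#' Read a 10x-style sparse matrix-market triplet
#'
#' Reads a `coordinate general` matrix-market file plus gene and barcode ID
#' files (one ID per line; only the first tab-separated column of the gene
#' file is used, matching the CellRanger v2 `genes.tsv` layout).
#'
#' @param matrix_path path to the `.mtx` file.
#' @param genes_path path to the gene ID file (rows of the matrix).
#' @param barcodes_path path to the cell barcode file (columns).
#' @return An `"expr_mat"` with sparse values, `scale = "raw_counts"`,
#'   `platform = "droplet"`.
#' @export
read_expression_10x <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  hdr <- tolower(readLines(matrix_path, n = 1L))
  if (!grepl("^%%matrixmarket\\s+matrix\\s+coordinate\\s+(real|integer)\\s+general\\s*$",
             hdr))
    stop("unsupported matrix-market dialect (coordinate general required): ",
         hdr)
  mm <- Matrix::readMM(matrix_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")[[1L]]
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "",
                                comment.char = "")[[1L]]
  if (length(genes) != nrow(mm))
    stop(sprintf("gene file has %d IDs but matrix header declares %d rows",
                 length(genes), nrow(mm)))
  if (length(barcodes) != ncol(mm))
    stop(sprintf("barcode file has %d IDs but matrix header declares %d columns",
                 length(barcodes), ncol(mm)))
  expression_matrix(methods::as(mm, "CsparseMatrix"), genes, barcodes,
                    scale = "raw_counts", platform = "droplet")
}

#' Write an expression matrix as a 10x-style triplet
#'
#' @param m an `"expr_mat"` object.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv` and `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_expression_10x <- function(m, dir) {
  stopifnot(inherits(m, "expr_mat"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(paste(m$gene_ids, m$gene_ids, sep = "\t"),
             file.path(dir, "genes.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Library-size normalize and log2-transform raw counts
#'
#' Scales every cell (column) to a common total, then applies
#' `log2(x + pseudocount)`. Cells whose total count is zero cannot be
#' scaled; they are left all-zero and a warning reports how many. With the
#' default `pseudocount = 1` zeros map to zero, so sparse inputs stay
#' sparse.
#'
#' @param m an `"expr_mat"` with `scale = "raw_counts"`.
#' @param size_factor_target per-cell total after scaling, default 1e4.
#' @param pseudocount positive offset inside the log, default 1.
#' @return An `"expr_mat"` with `scale = "log"`.
#' @export
log_normalize <- function(m, size_factor_target = 1e4, pseudocount = 1) {
  stopifnot(inherits(m, "expr_mat"),
            size_factor_target > 0, pseudocount > 0)
  if (m$scale == "log")
    stop("matrix is already log-scaled; refusing to transform twice")
  if (m$scale != "raw_counts")
    stop("log_normalize expects scale = 'raw_counts', got '", m$scale, "'")
  v <- m$values
  totals <- Matrix::colSums(v)
  zero <- totals == 0
  if (any(zero))
    warning(sum(zero), " cell(s) have zero total counts; left all-zero")
  sf <- ifelse(zero, 1, size_factor_target / totals)
  if (methods::is(v, "sparseMatrix") && pseudocount == 1) {
    v <- methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
    v@x <- v@x * rep.int(sf, diff(v@p))
    v@x <- log2(v@x + 1)
  } else {
    v <- as.matrix(v)
    v <- sweep(v, 2L, sf, `*`)
    v <- log2(v + pseudocount)
    v[, zero] <- 0   # zero-total cells stay all-zero even if pseudocount != 1
  }
  expression_matrix(v, m$gene_ids, m$cell_ids, scale = "log",
                    platform = m$platform)
}
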