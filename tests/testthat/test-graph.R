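log_mat <- function(v, ids = NULL) {
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(v)))
  expression_matrix(v, ids, paste0("c", seq_len(ncol(v))), scale = "log")
}

test_that("binarize thresholds strictly at each gene's mean", {
  m <- log_mat(rbind(c(1, 3, 2, 2), c(2, 2, 8, 0)))
  b <- binarize(m)
  expect_equal(unname(as.matrix(b$x)[1, ]), c(0, 1, 0, 0))  # mean 2, strict
  expect_equal(unname(as.matrix(b$x)[2, ]), c(0, 0, 1, 0))  # mean 3
  expect_equal(b$gene_means, c(2, 3))
  # constant row must be rejected (should have been excluded upstream)
  expect_error(binarize(log_mat(rbind(c(1, 3), c(2, 2)))), "all-0 or all-1")
  expect_error(binarize(expression_matrix(matrix(1:4, 2, 2),
                                          c("a", "b"), c("c1", "c2"))),
               "log")
})

test_that("binarized rows are never all-on or all-off", {
  set.seed(4)
  v <- matrix(pmax(rnorm(300, 1, 1), 0), 15, 20)
  b <- binarize(log_mat(v))
  rs <- Matrix::rowSums(b$x)
  expect_true(all(rs >= 1 & rs <= 19))
})

test_that("sparse and dense binarization agree", {
  set.seed(8)
  v <- matrix(rpois(200, 1) * runif(200), 10, 20)
  v[, 1] <- v[, 1] + 2   # avoid constant rows by construction? ensure below
  keep <- apply(v, 1, function(r) length(unique(r)) > 1)
  v <- v[keep, , drop = FALSE]
  bd <- binarize(log_mat(v))
  bs <- binarize(expression_matrix(Matrix::Matrix(v, sparse = TRUE),
                                   paste0("g", seq_len(nrow(v))),
                                   paste0("c", 1:20), scale = "log"))
  expect_equal(as.matrix(bd$x), as.matrix(bs$x), ignore_attr = TRUE)
})

test_that("co-occurrence counts match hand and brute-force results", {
  X <- rbind(c(1, 1, 0), c(1, 0, 1))
  S <- cooccurrence(binary_matrix(X))
  expect_equal(unname(S$counts), matrix(c(2L, 1L, 1L, 2L), 2, 2))
  # disjoint rows have zero off-diagonal
  S2 <- cooccurrence(binary_matrix(rbind(c(1, 0), c(0, 1))))
  expect_equal(unname(S2$counts), diag(1L, 2))
  set.seed(14)
  for (rep in 1:10) {
    X <- random_binary(sample(3:20, 1), sample(5:50, 1))
    S <- cooccurrence(binary_matrix(X))$counts
    expect_identical(unname(S), cooccurrence_brute(X))
    expect_identical(S, t(S))
    expect_equal(unname(diag(S)), rowSums(X))
  }
})

test_that("mutual-exclusivity counts match brute force and conservation", {
  X <- rbind(c(1, 1, 0), c(1, 0, 1))
  M <- mutual_exclusive(binary_matrix(X))$counts
  expect_equal(M[1, 2], 1L)
  expect_equal(M[2, 1], 1L)
  expect_equal(diag(M), c(g1 = 0L, g2 = 0L))
  # identical rows are never mutually exclusive
  M2 <- mutual_exclusive(binary_matrix(rbind(c(1, 0, 1), c(1, 0, 1))))$counts
  expect_true(all(M2 == 0))
  set.seed(15)
  for (rep in 1:10) {
    X <- random_binary(sample(3:20, 1), sample(5:50, 1))
    b <- binary_matrix(X)
    S <- cooccurrence(b)$counts
    M <- mutual_exclusive(b)$counts
    expect_identical(unname(M), mutual_exclusive_brute(X))
    # conservation: M[i,j] + S[i,j] = S[j,j]
    expect_identical(M + S,
                     matrix(diag(S), nrow(S), ncol(S), byrow = TRUE,
                            dimnames = dimnames(S)))
  }
})

test_that("neighbour graph applies threshold then top-k with index ties", {
  C <- matrix(0L, 4, 4)
  C[1, ] <- c(9L, 5L, 3L, 1L)   # A's row: B:5 C:3 D:1
  pc <- ambimark:::new_pair_counts(C, LETTERS[1:4], "cooccurrence")
  g <- neighbor_graph(pc, k = 2, n = 2)
  e <- g$edges[g$edges$from == 1, ]
  expect_equal(e$to, c(2L, 3L))          # D fails the n threshold
  expect_equal(e$weight, c(5L, 3L))
  # ties at the cut break by ascending gene index
  C2 <- matrix(0L, 4, 4)
  C2[1, 2:4] <- c(7L, 7L, 7L)
  g2 <- neighbor_graph(ambimark:::new_pair_counts(C2, LETTERS[1:4],
                                                  "cooccurrence"),
                       k = 2, n = 1)
  expect_equal(g2$edges$to[g2$edges$from == 1], c(2L, 3L))
  # all counts below n: empty graph
  g3 <- neighbor_graph(pc, k = 2, n = 100)
  expect_equal(nrow(g3$edges), 0L)
  expect_error(neighbor_graph(pc, k = 0, n = 1))
})

test_that("neighbour graph matches brute-force top-k on random counts", {
  set.seed(16)
  for (rep in 1:10) {
    N <- sample(4:15, 1)
    X <- random_binary(N, 40)
    S <- cooccurrence(binary_matrix(X))
    k <- sample(1:4, 1); n <- sample(1:8, 1)
    g <- neighbor_graph(S, k, n)
    for (a in seq_len(N)) {
      expect_equal(g$edges$to[g$edges$from == a],
                   topk_brute(S$counts[a, ], a, k, n))
    }
    expect_true(all(table(factor(g$edges$from, levels = seq_len(N))) <= k))
    expect_true(all(g$edges$weight >= n))
    expect_true(all(g$edges$from != g$edges$to))
  }
})

test_that("reciprocal pairs require bidirectional edges and record kind", {
  X <- two_module_binary()
  b <- binary_matrix(X)
  g_con <- neighbor_graph(cooccurrence(b), k = 2, n = 5)
  g_mex <- neighbor_graph(mutual_exclusive(b), k = 2, n = 5)
  pairs <- reciprocal_pairs(g_con, g_mex)
  con <- pairs[pairs$kind %in% c("cooccurrence", "both"), ]
  expect_setequal(paste(con$a, con$b),
                  c("1 2", "1 3", "2 3", "6 7"))
  mex <- pairs[pairs$kind %in% c("mutual_exclusive", "both"), ]
  expect_setequal(paste(mex$a, mex$b),
                  c("1 6", "1 7", "2 6", "2 7"))
  # a one-way edge is not a pair
  C <- matrix(0L, 2, 2); C[1, 2] <- 10L
  g1 <- neighbor_graph(ambimark:::new_pair_counts(C, c("a", "b"),
                                                  "cooccurrence"), 1, 1)
  expect_equal(nrow(reciprocal_pairs(g1)), 0L)
})

test_that("raising n only removes edges and shrinks the pair set", {
  set.seed(17)
  X <- random_binary(20, 100, p = 0.4)
  b <- binary_matrix(X)
  S <- cooccurrence(b); M <- mutual_exclusive(b)
  prev_edges <- NULL; prev_pairs <- NULL
  for (n in c(5, 15, 30, 45)) {
    g_con <- neighbor_graph(S, k = 5, n = n)
    g_mex <- neighbor_graph(M, k = 5, n = n)
    edges <- paste(g_con$edges$from, g_con$edges$to)
    pairs <- reciprocal_pairs(g_con, g_mex)
    keys <- paste(pairs$a, pairs$b)
    if (!is.null(prev_edges)) {
      expect_true(all(edges %in% prev_edges))
      expect_true(all(keys %in% prev_pairs))
    }
    prev_edges <- edges; prev_pairs <- keys
  }
})

test_that("select_markers composes the stages end to end", {
  set.seed(21)
  sim <- simulate_cells(n_cells = 200, n_genes = 120, n_marker_genes = 16,
                        seed = 77)
  fit <- select_markers(sim$expression, k = 50, n = 15)
  expect_s3_class(fit, "marker_selection")
  # markers are a subset of the multimodal genes, which are input genes
  expect_true(all(fit$markers %in% names(fit$profiles)))
  expect_true(all(names(fit$profiles) %in% sim$expression$gene_ids))
  expect_false(anyDuplicated(fit$markers) > 0)
  expect_equal(fit$markers, fit$provenance$gene_id)
  expect_true(all(fit$provenance$n_partners >= 1))
  expect_true(all(fit$provenance$peak_count >= 2))
  # noise-only matrix yields a near-empty marker set
  noise <- simulate_cells(n_cells = 200, n_genes = 120,
                          n_marker_genes = 2, marker_shift = 0, seed = 5)
  fit0 <- suppressWarnings(select_markers(noise$expression, k = 50, n = 15))
  expect_lte(length(markers(fit0)), 6)
})

test_that("marker set is invariant under cell permutation and equivariant under gene permutation", {
  sim <- simulate_cells(n_cells = 150, n_genes = 80, n_marker_genes = 12,
                        seed = 42)
  m <- sim$expression
  fit <- select_markers(m, k = 40, n = 10)
  set.seed(1)
  perm <- sample(ncol(m$values))
  m_cells <- expression_matrix(m$values[, perm], m$gene_ids,
                               m$cell_ids[perm], scale = "log")
  expect_equal(markers(select_markers(m_cells, k = 40, n = 10)),
               markers(fit))
  gperm <- sample(nrow(m$values))
  m_genes <- expression_matrix(m$values[gperm, ], m$gene_ids[gperm],
                               m$cell_ids, scale = "log")
  expect_setequal(markers(select_markers(m_genes, k = 40, n = 10)),
                  markers(fit))
})

test_that("marker and graph outputs write as plain text", {
  sim <- simulate_cells(n_cells = 150, n_genes = 60, n_marker_genes = 10,
                        seed = 3)
  fit <- select_markers(sim$expression, k = 30, n = 10)
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_markers(fit, prefix, edges = TRUE)
  expect_equal(readLines(paths["markers"]), fit$markers)
  prov <- read.delim(paths["provenance"])
  expect_equal(prov$gene_id, fit$provenance$gene_id)
  edges <- read.delim(paths["edges"])
  expect_setequal(unique(edges$graph_kind),
                  c("cooccurrence", "mutual_exclusive"))
})
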