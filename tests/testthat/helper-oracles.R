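# Independent brute-force oracles. These implement the definitions
# literally (double loops, per-point window scans) and are kept separate
# from the code paths they check.

# Gaussian KDE as a literal double loop
kde_brute <- function(values, h, grid) {
  L <- length(values)
  dens <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (j in seq_len(L)) s <- s + stats::dnorm((grid[i] - values[j]) / h)
    dens[i] <- s / (L * h)
  }
  dens
}

# sliding-window peak rule as an exhaustive per-point scan: point c is a
# peak when density(c) >= density(g) for every grid point g within
# [c - h, c + h]; adjacent qualifying points collapse to one plateau-peak
peaks_brute <- function(grid, density, h) {
  G <- length(grid)
  is_peak <- logical(G)
  for (i in seq_len(G)) {
    win <- which(grid >= grid[i] - h & grid <= grid[i] + h)
    is_peak[i] <- all(density[win] <= density[i])
  }
  r <- rle(is_peak)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- starts[r$values]
  list(count = length(idx), positions = grid[idx])
}

# pairwise AND count, literal loops over gene pairs and cells
cooccurrence_brute <- function(X) {
  N <- nrow(X)
  S <- matrix(0L, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    S[i, j] <- sum(X[i, ] == 1 & X[j, ] == 1)
  S
}

# pairwise (NOT-A AND B) count
mutual_exclusive_brute <- function(X) {
  N <- nrow(X)
  M <- matrix(0L, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    M[i, j] <- sum(X[i, ] == 0 & X[j, ] == 1)
  M
}

# threshold-then-top-k neighbour selection for one source gene
topk_brute <- function(counts_row, a, k, n) {
  cand <- setdiff(which(counts_row >= n), a)
  if (!length(cand)) return(integer(0))
  cand[order(-counts_row[cand], cand)][seq_len(min(k, length(cand)))]
}

# density profile wrapper for hand-built density vectors
new_profile_for_test <- function(grid, density, h = 0.1) {
  ambimark:::new_density_profile("test", grid, density, h)
}

# random binary matrix whose every row has at least one 0 and one 1
random_binary <- function(n_genes, n_cells, p = 0.3) {
  X <- matrix(rbinom(n_genes * n_cells, 1, p), n_genes, n_cells)
  X[, 1] <- 1L
  X[, 2] <- 0L
  X
}

# binary matrix realizing the schematic two-module pattern: genes 1-3 on
# together in cells 1-10, genes 6-7 on together in cells 11-20, genes 4-5
# scattered below any sensible support threshold
two_module_binary <- function() {
  X <- matrix(0L, 7, 20)
  X[1:3, 1:10] <- 1L
  X[6:7, 11:20] <- 1L
  X[4, c(1, 2, 11, 12)] <- 1L
  X[5, c(3, 13)] <- 1L
  rownames(X) <- paste0("g", 1:7)
  X
}
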