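# ambimark

Annotation-free (*ab initio*) selection of cell-type-discriminative marker
genes from single-cell RNA-seq expression matrices, for analysts who need
an informative gene subset *before* clustering — without reference
profiles, known cell types, or a first clustering pass.

## The method

In a mixture of cell types, a genuine marker gene must look different from
a noise gene in two ways, both visible in the matrix alone:

**Multimodality.** The per-cell expression density of each gene
(log scale) is estimated with an exact Gaussian kernel sum,

    f_h(g) = (1 / (L h)) * sum_j K((g - g_j) / h),

with `L` cells and bandwidth `h` (0.3 for plate/full-transcript data,
0.05 for 3' droplet data, or the per-gene normal-reference rule
`h = (4 sigma^5 / (3 L))^(1/5)`). A point `c` is a *peak* if the density
nowhere exceeds `f_h(c)` on the window `[c - h, c + h]`; genes with `T >= 2`
peaks — an off mass plus at least one on mode — pass. Unimodal genes are
discarded.

**Reciprocal pairing.** The multimodal submatrix is binarized at each
gene's mean (`x_ij = 1` iff expression strictly above the gene's average),
giving `X` in `{0,1}^(N x L)`. Pairwise cell counts

    S = X X'          (both genes on: co-occurrence)
    M = (1 - X) X'    (first off, second on: mutual exclusivity)

induce two directed k-nearest-neighbour gene graphs: an edge `A -> B`
needs at least `n` supporting cells, and only the `k` strongest neighbours
per gene are kept (defaults `k = 300`, `n = 30`). **Markers are the genes
in at least one bidirectionally connected pair** in either graph — genes
whose on/off pattern is coordinated with some other gene's, the signature
of a cell-type program rather than random fluctuation.

The package also provides the two canonical baselines (highest mean
expression; highest variance or binned dispersion), clustering-based
evaluation with the adjusted Rand index, a planted-marker simulator, a
`(k, n)` sweep utility, and a command-line interface.

## Worked example

```r
library(ambimark)

# 300 cells in two equal populations; 20 of 200 genes are true markers
sim <- simulate_cells(n_cells = 300, n_genes = 200, n_marker_genes = 20,
                      seed = 7)
fit <- select_markers(sim$expression, k = 100, n = 20)
fit
#> Marker selection by multimodality and reciprocal gene pairing
#>   parameters: k = 100, n = 20, h = 0.3 (fixed)
#>   genes: 200 input -> 20 multimodal -> 20 markers
#>   markers: gene0001, gene0002, gene0003, gene0004, gene0005, ...

marker_recovery(markers(fit), sim$markers)
#> precision    recall
#>         1         1

lab <- cluster_cells(sim$expression, markers(fit), n_clusters = 2, seed = 7)
adjusted_rand_index(lab, sim$labels)
#> [1] 1
```

Reading the output: of 200 genes, exactly the 20 with bimodal expression
survive the density filter, and all 20 pair reciprocally (the 10 markers
of each population co-occur with each other — 90 co-occurrence pairs —
and are mutually exclusive with the other population's 10 — 100
mutual-exclusivity pairs, visible in `summary(fit)`). Precision and
recall against the planted truth are both 1, and k-means on the selected
genes reproduces the true populations exactly (ARI = 1).

For real data, start from a file instead:

```r
m <- read_expression("counts.tsv")            # or read_expression_10x(...)
m <- log_normalize(m)                         # to 1e4 per cell, log2(x + 1)
fit <- select_markers(m)                      # k = 300, n = 30, platform h
write_markers(fit, "run1", edges = TRUE)
```

or from a shell:

```sh
Rscript inst/cli/ambimark.R select --input counts.tsv --platform smart_seq \
    --k 300 --n 30 --out run1
Rscript inst/cli/ambimark.R benchmark --seeds 1,2,3 --out bench
Rscript inst/cli/ambimark.R sweep --input counts.tsv --scale log \
    --k-range 50:1000:50 --n-range 5:100:5 --out grid
```

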