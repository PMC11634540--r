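# sch5 — a unified HDF5 container for single-cell data

Single-cell analysis is split between Seurat (R) and Scanpy/AnnData
(Python), which disagree on matrix orientation, factor encoding and object
layout, so moving a dataset between them routinely loses structure or fails
outright. **sch5** implements an explicit, validated HDF5 (`.h5`) schema
both ecosystems can share, and the R tooling around it: an in-memory
container model, a bit-exact sparse codec, full-file validation, a Seurat
adapter, a deterministic synthetic-data generator and a small CLI.

The core of the format is **blocked compressed-sparse-row storage**. A
layer is stored as CSR triplets — `data` (nonzero values), `indices`
(0-based column indices), `indptr` (row-start offsets, `indptr[i+1] −
indptr[i]` = nonzeros in row *i*) — with the rows partitioned into blocks of
5000 cells. Because a block's `indptr` is bounded by the *block's* nonzero
count, every stored index pointer stays inside R's signed 32-bit integer
range even when the whole matrix exceeds 2³¹ − 1 nonzeros; any array whose
actual maximum does cross the boundary is written as 64-bit automatically.
Annotation tables store factors as `categories` (ordered unique levels) +
`codes` (0-based, −1 = missing); embeddings, `nn`/`snn` neighbor graphs and
Visium-style spatial samples (image + per-spot full-resolution pixel
coordinates + scale factors) have dedicated groups.

## Worked example

```r
library(sch5)

# a realistic synthetic dataset: sparse counts, 3 cell types, PCA + UMAP,
# nn/snn graphs, and a Visium-style spatial sample
x <- make_container(n_cells = 1000, n_genes = 500, with_spatial = TRUE, seed = 42)
x
#> <sc_container> 1000 cells x 500 genes
#>   assay RNA: layers counts
#>   obs: 3 column(s); var: 2 column(s)
#>   reductions: pca (50d), umap (2d)
#>   graphs: nn, snn
#>   spatial samples: sample1

write_h5(x, "pbmc_like.h5")
describe_h5("pbmc_like.h5")
#> sch5 file: 1000 cells x 500 genes (format 1.0)
#>   layer RNA/counts: csr_blocked, 24995 nonzeros
#>   reduction pca: 50 dims
#>   reduction umap: 2 dims
#>   graph nn: 10000 nonzeros
#>   graph snn: 203854 nonzeros
#>   spatial samples: sample1

# reading back reproduces every component exactly (counts bit-for-bit,
# factor level order, embeddings, graph weights, image bytes)
y <- read_h5("pbmc_like.h5")
length(container_diff(x, y))
#> [1] 0

# or load straight into the host analysis object
seu <- load_h5("pbmc_like.h5", read_type = "seurat")

# validation reports violations as data, one record per broken rule
bad <- make_corrupted_file("pbmc_like.h5", "shuffle_indptr")
validate_h5(bad)
#>                                   path                     rule
#> 1 /assay/RNA/counts/block_00000/indptr indptr_not_nondecreasing
#>                       message
#> 1 indptr is not nondecreasing
```

The 24995 nonzeros correspond to the requested 5% density (1000 × 500 ×
0.05); `nn` holds exactly k = 10 directed neighbor edges per cell, and
`snn` their Jaccard-weighted shared-neighbor overlaps.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "sch5.R", package = "sch5"))') \
    fixtures make --cells 1000 --genes 500 --seed 42 --spatial -o fixture.h5
... validate fixture.h5     # conformance report, exit 0 iff clean
... info fixture.h5         # key=value summary
... convert fixture.h5 out.h5 --block-size 100   # lossless re-blocking
```

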