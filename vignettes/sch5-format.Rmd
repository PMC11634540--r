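---
title: "The sch5 container format: design and rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sch5 container format: design and rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell RNA-seq analysis is split across two ecosystems: Seurat in R and
Scanpy/AnnData in Python. They disagree on matrix orientation (Seurat holds
genes × cells `dgCMatrix`, i.e. column-compressed; Scanpy holds cells × genes
CSR), on factor encoding (R factors are 1-based, pandas categoricals
0-based), and on where annotations, embeddings, neighbor graphs and spatial
images live. Serialized objects (`.rds`, `.h5ad`) do not transfer cleanly,
and ad hoc converters break whenever either ecosystem changes its object
model. sch5 defines one explicit HDF5 schema that both sides can read and
write, and implements the R side: an ecosystem-neutral in-memory container,
a bit-exact codec, full-file validation, and a Seurat adapter.

## The schema

A conforming `.h5` file has at its root two string datasets, `names_obs`
(cell names) and `names_var` (gene names), and the groups `assay`, `obs`,
`var`, `reductions` and `graphs`; an `images` group is present only when the
file carries spatial data — absent optional components are absent groups,
never empty ones. A `format_version` attribute on the root identifies the
layout.

### Sparse matrices: blocked CSR

Raw single-cell counts are overwhelmingly zero — each cell type expresses
its own modest gene program and dropout removes much of the rest — so
expression layers and cell–cell graphs are stored sparse, as CSR triplets:

* `data` — the nonzero values,
* `indices` — the 0-based column index of each value,
* `indptr` — the 0-based offset where each row starts
  (`length = n_rows + 1`, nondecreasing, first element 0).

Canonical form (indices strictly increasing within each row, no explicit
zeros, no duplicates) is enforced on encode and on read, which is what makes
round-trip comparisons bit-exact rather than merely numerically equal.

The pitfall this format exists to avoid: R's native integers are signed
32-bit, and `indptr` of a large matrix is bounded by the total nonzero
count, which multi-million-cell datasets exceed. sch5 therefore partitions
the rows into fixed-size blocks — 5000 cells by default — and stores each
block as an independent triplet under `block_00000`, `block_00001`, ….
A block's `indptr` is bounded by the *block's* nonzero count (at 5000 cells
it would take ~430,000 genes of dense expression to overflow), so 32-bit
indices almost always suffice; when an array's actual maximum does exceed
`2^31 - 1` it is transparently written as 64-bit. Width is selected per
stored array from its actual maximum, never globally, so small files stay
small. Blocking is applied unconditionally (a small matrix is simply one
block) — one code path, no special cases — and to graphs as well as
expression layers, for uniformity. The boundary itself is exposed as a
parameter (`int32_max`) so the overflow machinery is exercisable at desk
scale; a genuinely >2^31-nonzero matrix is not a reasonable test fixture.

Orientation is cells × genes (row-compressed over cells) everywhere in the
model and on disk. Column-oriented hosts transpose exactly once, at the
adapter boundary; a single canonical orientation avoids the classic
double-transposition bugs of format converters. `transpose_triplet()` is
the boundary operation: the CSR of the transpose is precisely the CSC
(`dgCMatrix`) layout of the original.

### Annotation tables

`obs` and `var` hold one dataset per column, each tagged with a `kind`
attribute (`numeric`, `integer`, `boolean`, `string`, `factor`); an explicit
marker, because inferring kind from content is ambiguous (is a string column
a factor?). Factor columns are subgroups holding `categories` (the ordered
unique level strings) and `codes` (0-based references, `-1` = missing).
Category order is first-appearance / user-defined level order, never
lexicographic, so deliberate level orderings (e.g. ordered cluster labels)
survive; unused levels are retained. Row names live in `_index` inside the
group *and* in the root name datasets; the root is authoritative and any
disagreement is a validation violation rather than a silent preference.

Missing-value policy, chosen to be unambiguous and testable: numeric
columns may hold `NA` (stored as an IEEE NaN payload, which HDF5 round-trips
bit-exactly; other readers see NaN); factor columns use code `-1`; integer,
boolean and plain string columns must be complete — an integer column with
gaps should be numeric, a string column with gaps a factor. Booleans are
stored as 8-bit integers for portability.

Column insertion order is recorded in a `column_order` attribute since HDF5
listings are alphabetical; the same `element_order` device preserves the
order of assays, layers, reductions and graphs.

### Reductions, graphs, spatial

Each reduction (`pca`, `umap`, `harmony`, …) is one dense
`n_cells × n_dims` dataset under `reductions`, with an optional
`dim_labels` attribute carrying the column labels (`PC_1`, …). Graphs
(`nn`, the k-nearest-neighbor graph; `snn`, the shared-nearest-neighbor
graph used for clustering) are square blocked-CSR matrices over cells with
nonnegative finite weights.

Spatial samples (Visium-style) live at `images/<sample>/` with an `image`
dataset (`H × W × 3` uint8; the axis convention — and which resolution the
image is — is recorded in attributes, because a silent x/y swap is the most
common spatial-conversion bug), a `coords` dataset (`n_spots × 2`
full-resolution pixel positions, row order aligned to the cell order), and
a `scale_factors` group of positive scalars. The four standard Visium keys
are required; extras are preserved verbatim. Spots outside the image after
rounding warn rather than error — fiducial margins legitimately place spots
beyond the cropped tissue image.

## Validation philosophy

`validate_container()` (in memory) and `validate_h5()` (on disk) return
violations as data — one record per broken rule, naming the object and the
rule — and never throw on content problems. `read_h5()` validates first and
refuses a nonconforming file, so reading succeeds exactly when the report is
empty. Checks whose premises are broken are skipped rather than cascaded: a
missing `names_obs` suppresses every check that needs the cell count, a
non-square graph suppresses that graph's block checks. Each planted defect
therefore surfaces as exactly one violation, which is what makes the
corruption fixtures (`make_corrupted_file()`) a precise probe of error-path
coverage.

## The synthetic generator

`make_container()` is first-class, tested code, and its defaults are the
reference conditions used throughout the test suite: 1000 cells × 500 genes
at density 0.05, 3 cell types, 50-d PCA-like and 2-d UMAP-like embeddings,
`nn`/`snn` graphs with k = 10, seed 42. It emulates the *structure* of real
data: counts are drawn per cell by choosing ~density × n_genes expressed
genes with cell-type-weighted probabilities (each type overexpresses a
dedicated gene slice) and negative-binomial values (size 2, mean 5, shifted
to ≥ 1); `obs` carries a factor (cell type), a numeric consistent with the
matrix (`total_counts` = row sums) and a string column; graphs are exact
k-nearest-neighbor graphs on the embedding, with Jaccard-weighted shared
neighbors for `snn`; the spatial fixture is a 64 × 64 × 3 random image with
one in-bounds spot per cell and the four standard scale factors. The same
seed always yields the identical container and the caller's RNG state is
restored.

What it does *not* emulate — and hence what passing tests do not show —
are the statistical properties of real data: no gene–gene correlation
structure, no library-size variation, no batch effects, no spatial
autocorrelation, no meaningful embedding geometry beyond coarse type
separation. The tests establish that the codec is lossless and the
validator sharp, not that any biological signal is preserved in an
analysis-relevant sense (nothing in a lossless codec could lose it, but the
fixtures cannot demonstrate it either).

Test and verification problem sizes (1000 × 500 for the flagship round
trip, 300 cells for the block-size sweep, 200 oracle matrices ≤ 20 × 20,
500 factor columns) were chosen so the whole suite completes in about a
minute while still crossing every block boundary and density corner.

## Host adapters

`to_seurat()` / `as_sc_container()` map the container onto Seurat v5:
layers transpose to genes × cells `dgCMatrix`, `obs` becomes `meta.data`,
`var` the assay's feature-level metadata, reductions become `DimReduc`
objects and graphs `Graph` objects. Factor codes shift between 0-based
(disk) and 1-based (R) at this boundary. Host components outside the model
(`commands`, `tools`, caches in `misc`, assays whose feature set differs
from the default assay's) are dropped with an explicit notice and an
enumerating `"dropped"` attribute — explicit loss beats silent loss.

Two documented adapter limitations. First, Seurat's Visium image classes
(`VisiumV2`) cannot be constructed from raw parts through any supported
public interface, so spatial blocks travel through `@misc$sch5_spatial`
(with a notice) instead of `@images`; the on-disk format and the container
model are unaffected. Second, a reduction with no dimension labels acquires
key-derived labels (`pca_1`, …) on the way through Seurat, since Seurat
requires them; labeled reductions round-trip unchanged. Seurat also rejects
underscores in feature names (it rewrites them to dashes), which is a host
constraint, not a format one — the fixtures use dash-separated names.

`readType`-style dispatch is exposed as `load_h5(path, read_type)` with
targets `"seurat"` (the default: users load straight into their analysis
object) and `"container"` (always available, ecosystem-free). The Python
side of the ecosystem reads the same schema with h5py/anndata; implementing
that reader is out of scope here, but the schema choices above (explicit
kind markers, UTF-8 strings, little-endian numerics, 0-based codes) were
made so that nothing in the file is R-specific.

## Numerical and degenerate-input choices

* Values are stored as 64-bit floats (what both `dgCMatrix` and dense R
  matrices hold natively), so "round trip" means `identical()`, not
  `all.equal()`.
* Zero-row/zero-column matrices, empty tables, zero-length factor columns
  and containers with no reductions/graphs are all legal and tested;
  zero-length HDF5 datasets are written contiguous (a chunked dataset
  cannot have a zero-size chunk).
* `decode_csr` checks all triplet invariants and names the violated rule;
  ties in the k-NN fixture graph are broken by index order, making the
  generator deterministic across platforms with the same RNG.
* gzip level 4 is the compression default: within a few percent of level 9
  on sparse count data at a fraction of the write time, and configurable
  per call.

## Known limitations

* No lazy/partial reads and no on-disk matrix backend; a file is read into
  memory as a whole. Very large matrices are out of scope for the in-memory
  model (the blocked layout is ready for a streaming reader, which would be
  an additive change).
* No byte-level compatibility claim with any third-party dialect's exact
  attribute spelling; the schema is normative here, and `validate_h5()` is
  its executable definition.
* One gene universe per container: multi-assay objects are supported only
  when assays share the feature set (the adapter drops others, loudly).
* `NA` and `NaN` in numeric columns both survive on disk, but non-R readers
  will see both as NaN; code that distinguishes them does not port.
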