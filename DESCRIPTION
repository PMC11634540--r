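Package: sch5
Title: Unified HDF5 Container for Cross-Platform Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Read, write and validate a unified HDF5 (.h5) container for
    single-cell and spatial transcriptomics data, designed for lossless
    exchange between the R (Seurat) and Python (Scanpy/AnnData) ecosystems.
    Expression layers and cell-cell graphs are serialized as canonical
    compressed-sparse-row triplets partitioned into fixed-size row blocks so
    that per-block index pointers stay within the 32-bit integer range even
    for very large datasets; annotation tables use an explicit
    categories/codes factor encoding; dimensionality reductions, neighbor
    graphs and Visium-style spatial images with spot coordinates and scale
    factors are stored in dedicated groups. Includes full-file schema
    validation, a deterministic synthetic-data generator for testing, a
    Seurat adapter, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    Seurat,
    SeuratObject,
    jsonlite
Config/testthat/edition: 3
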