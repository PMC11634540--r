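test_that("a full container round-trips exactly, including a dense layer", {
  x <- make_container(n_cells = 150, n_genes = 60, with_spatial = TRUE, seed = 21)
  # add a dense layer and a second assay to cover every layout branch
  x$assays$RNA$scaled <- matrix(
    rnorm(150 * 60), 150, 60,
    dimnames = list(x$cell_names, x$gene_names)
  )
  x$assays$ADT <- list(counts = x$assays$RNA$counts)
  f <- local_h5(x)
  y <- read_h5(f)
  expect_length(container_diff(x, y), 0)
  expect_equal(nrow(validate_container(y)), 0)
})

test_that("absent optional components produce absent groups, empty required ones stay", {
  x <- make_container(
    n_cells = 40, n_genes = 20, reductions = list(), graphs = character(0),
    seed = 3
  )
  f <- local_h5(x)
  expect_true(sch5:::h5_exists(f, "reductions"))
  expect_true(sch5:::h5_exists(f, "graphs"))
  expect_false(sch5:::h5_exists(f, "images"))
  y <- read_h5(f)
  expect_length(y$reductions, 0)
  expect_length(y$graphs, 0)
  expect_null(y$spatial)
})

test_that("write_h5 refuses an invalid container with the violation list", {
  x <- make_container(n_cells = 30, n_genes = 10, seed = 2)
  x$assays$RNA$counts <- x$assays$RNA$counts[, 1:9]
  err <- tryCatch(write_h5(x, tempfile(fileext = ".h5")), condition = identity)
  expect_s3_class(err, "sch5_validation_error")
  expect_equal(err$violations$rule, "layer_shape")
})

test_that("block size is an encoding detail: all block sizes read back equal", {
  x <- make_container(n_cells = 101, n_genes = 30, seed = 13)
  ref <- NULL
  for (bs in c(1, 7, 100, 5000)) {
    f <- tempfile(fileext = ".h5")
    write_h5(x, f, block_size = bs)
    at <- sch5:::h5_attrs(f, "assay/RNA/counts")
    expect_equal(as.double(at$n_blocks), ceiling(101 / bs))
    y <- read_h5(f)
    expect_length(container_diff(x, y), 0)
    if (is.null(ref)) ref <- y else expect_length(container_diff(ref, y), 0)
    unlink(f)
  }
})

test_that("missing required pieces surface as named schema errors", {
  x <- make_container(n_cells = 25, n_genes = 10, seed = 5)
  f <- local_h5(x)
  rhdf5::h5delete(f, "names_obs")
  v <- validate_h5(f)
  expect_equal(nrow(v), 1)
  expect_equal(v$rule, "missing_dataset")
  expect_equal(v$path, "/names_obs")
  expect_error(read_h5(f), "missing /names_obs", class = "sch5_schema_error")
})

test_that("an unknown matrix encoding is reported, not guessed at", {
  x <- make_container(n_cells = 25, n_genes = 10, seed = 5)
  f <- local_h5(x)
  rhdf5::h5deleteAttribute(f, "assay/RNA/counts", "encoding")
  sch5:::h5_put_attr(f, "assay/RNA/counts", "encoding", "csc_blocked")
  v <- validate_h5(f)
  expect_equal(v$rule, "unknown_encoding")
  expect_error(read_h5(f), class = "sch5_schema_error")
})

test_that("validate_h5 emptiness coincides with read_h5 success", {
  x <- make_container(n_cells = 30, n_genes = 12, with_spatial = TRUE, seed = 9)
  f <- local_h5(x)
  expect_equal(nrow(validate_h5(f)), 0)
  expect_silent(y <- read_h5(f))
  for (m in c("shuffle_indptr", "nonsquare_graph")) {
    bad <- make_corrupted_file(f, m)
    expect_gt(nrow(validate_h5(bad)), 0)
    expect_error(read_h5(bad), class = "sch5_schema_error")
    unlink(bad)
  }
})

test_that("describe_h5 agrees with the container read back", {
  x <- make_container(n_cells = 80, n_genes = 40, with_spatial = TRUE, seed = 17)
  f <- local_h5(x)
  d <- describe_h5(f)
  y <- read_h5(f)
  expect_equal(d$n_cells, 80)
  expect_equal(d$n_genes, 40)
  expect_equal(d$assays$RNA$counts$nnz, Matrix::nnzero(y$assays$RNA$counts))
  expect_equal(d$reductions, list(pca = 50, umap = 2))
  expect_equal(d$graphs$nn, Matrix::nnzero(y$graphs$nn))
  expect_equal(d$spatial, "sample1")

  x2 <- make_container(n_cells = 20, n_genes = 10, seed = 1)
  d2 <- describe_h5(local_h5(x2))
  expect_length(d2$spatial, 0)
})

test_that("dimension labels and element order survive the round trip", {
  x <- make_container(
    n_cells = 30, n_genes = 15,
    reductions = list(umap = 2L, pca = 5L), # non-alphabetical order
    seed = 23
  )
  f <- local_h5(x)
  y <- read_h5(f)
  expect_equal(names(y$reductions), c("umap", "pca"))
  expect_equal(colnames(y$reductions$pca), paste0("PC_", 1:5))
  expect_equal(names(y$graphs), c("nn", "snn"))
})

test_that("index widths are chosen per array from the 32-bit boundary seam", {
  # 100 x 100 with exactly 50 nonzeros per row -> 5000 nonzeros
  m <- matrix(0, 100, 100)
  m[, 1:50] <- 1
  x <- sc_container(
    counts = Matrix::Matrix(m, sparse = TRUE),
    cell_names = sprintf("c%03d", 1:100), gene_names = sprintf("g%03d", 1:100)
  )

  # one block: whole-matrix indptr tops out at 5000 > 1000 -> 64-bit on disk
  f1 <- tempfile(fileext = ".h5")
  write_h5(x, f1, block_size = 5000, int32_max = 1000)
  expect_equal(sch5:::h5_type_size(f1, "assay/RNA/counts/block_00000/indptr"), 8)
  expect_equal(sch5:::h5_type_size(f1, "assay/RNA/counts/block_00000/indices"), 4)

  # 10-row blocks: per-block indptr <= 500 stays within the lowered bound
  f2 <- tempfile(fileext = ".h5")
  write_h5(x, f2, block_size = 10, int32_max = 1000)
  expect_equal(sch5:::h5_type_size(f2, "assay/RNA/counts/block_00000/indptr"), 4)

  # both decode to the same matrix
  expect_length(container_diff(read_h5(f1), read_h5(f2)), 0)
  unlink(c(f1, f2))
})
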