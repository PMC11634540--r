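test_that("encode_factor lists categories by first appearance with 0-based codes", {
  f <- encode_factor(c("T", "B", "T", "NK"))
  expect_equal(f$categories, c("T", "B", "NK"))
  expect_equal(f$codes, c(0L, 1L, 0L, 2L))

  e <- encode_factor(character(0))
  expect_length(e$categories, 0)
  expect_length(e$codes, 0)

  m <- encode_factor(c("A", NA, "A"))
  expect_equal(m$categories, "A")
  expect_equal(m$codes, c(0L, -1L, 0L))
})

test_that("encode_factor preserves explicit level order of factor input", {
  f <- encode_factor(factor(c("A", "B"), levels = c("B", "A", "Z")))
  expect_equal(f$categories, c("B", "A", "Z"))
  expect_equal(f$codes, c(1L, 0L))
})

test_that("decode_factor inverts encode_factor and keeps unused categories", {
  expect_equal(
    as.character(decode_factor(factor_column(c("A", "B"), c(1L, 0L)))),
    c("B", "A")
  )
  d <- decode_factor(factor_column(c("A", "B"), 0L))
  expect_equal(levels(d), c("A", "B")) # unused level retained
  expect_equal(as.character(d), "A")

  expect_error(
    decode_factor(factor_column(c("A", "B"), 2L)),
    "out of range at row 1",
    class = "sch5_validation_error"
  )
  expect_error(
    decode_factor(factor_column(c("A", "A"), 0L)),
    class = "sch5_validation_error"
  )
})

test_that("factor codec round-trips randomized columns against the scan oracle", {
  set.seed(202)
  pool <- c("a", "b", "naïve-T", "γδ-T", "x y", "")
  for (rep in 1:50) {
    n <- sample(0:50, 1)
    v <- sample(pool[-6], n, replace = TRUE)
    v[runif(n) < 0.3] <- NA
    f <- encode_factor(v)
    o <- oracle_encode_factor(v)
    expect_equal(f$categories, o$categories)
    expect_equal(f$codes, o$codes)
    expect_equal(as.character(decode_factor(f)), as.character(v))
  }
})

test_that("annotation tables round-trip exactly, preserving kinds and order", {
  df <- data.frame(
    score = c(1.5, NA, 3.25, 0, -2),
    n_genes = 1:5,
    pass_qc = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    barcode = sprintf("bc%d", 1:5),
    subtype = factor(c("naïve-T", "γδ-T", "naïve-T", NA, "γδ-T"),
      levels = c("γδ-T", "naïve-T", "unused-level")
    ),
    row.names = sprintf("cell-%d", 1:5), check.names = FALSE
  )
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  write_table(df, f, "obs")
  back <- read_table(f, "obs")
  expect_identical(back, df)
  expect_equal(levels(back$subtype), c("γδ-T", "naïve-T", "unused-level"))
})

test_that("zero-column tables keep their row names", {
  df <- data.frame(row.names = sprintf("r%d", 1:10))
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  write_table(df, f, "var")
  expect_identical(read_table(f, "var"), df)
})

test_that("column insertion order survives HDF5's alphabetical listing", {
  df <- data.frame(
    zebra = 1:3, alpha = c("x", "y", "z"), mid = c(0.5, 1.5, 2.5),
    row.names = c("a", "b", "c"), check.names = FALSE
  )
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  write_table(df, f, "obs")
  expect_equal(names(read_table(f, "obs")), c("zebra", "alpha", "mid"))
})

test_that("random tables round-trip exactly (property)", {
  set.seed(303)
  for (rep in 1:25) {
    df <- rand_table(sample(0:200, 1), sample(0:5, 1))
    f <- tempfile(fileext = ".h5")
    rhdf5::h5createFile(f)
    write_table(df, f, "obs")
    expect_identical(read_table(f, "obs"), df)
    unlink(f)
  }
})

test_that("incomplete non-factor columns and unknown kinds are refused", {
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  bad <- data.frame(s = c("a", NA), row.names = c("r1", "r2"))
  expect_error(write_table(bad, f, "obs"), class = "sch5_parameter_error")

  bad2 <- data.frame(x = I(list(1, 2)), row.names = c("r1", "r2"))
  expect_error(write_table(bad2, f, "obs"), class = "sch5_parameter_error")

  # unknown kind marker on disk -> schema error on read
  ok <- data.frame(x = 1:2, row.names = c("r1", "r2"))
  write_table(ok, f, "obs")
  rhdf5::h5deleteAttribute(f, "obs/x", "kind")
  sch5:::h5_put_attr(f, "obs/x", "kind", "mystery")
  expect_error(read_table(f, "obs"), "unknown kind", class = "sch5_schema_error")
})
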