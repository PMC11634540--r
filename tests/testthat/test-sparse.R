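test_that("encode_csr produces canonical triplets on known matrices", {
  t1 <- encode_csr(rbind(c(0, 1, 0), c(2, 0, 3)))
  expect_equal(t1$data, c(1, 2, 3))
  expect_equal(t1$indices, c(1, 0, 2))
  expect_equal(t1$indptr, c(0, 1, 3))
  expect_equal(t1$shape, c(2, 3))

  t2 <- encode_csr(matrix(0, 4, 4))
  expect_length(t2$data, 0)
  expect_length(t2$indices, 0)
  expect_equal(t2$indptr, rep(0, 5))

  t3 <- encode_csr(diag(3))
  expect_equal(t3$data, c(1, 1, 1))
  expect_equal(t3$indices, c(0, 1, 2))
  expect_equal(t3$indptr, c(0, 1, 2, 3))
})

test_that("encode_csr drops explicit zeros from sparse input", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(5, 0), dims = c(2, 2))
  t <- encode_csr(m)
  expect_equal(t$data, 5)
  expect_equal(sum(t$indptr[3]), 1)
})

test_that("encode_csr rejects non-2-D and non-finite input, naming the entry", {
  expect_error(encode_csr(1:5), class = "sch5_validation_error")
  m <- matrix(1, 2, 2)
  m[2, 1] <- NaN
  expect_error(encode_csr(m), "\\(2, 1\\)", class = "sch5_validation_error")
  s <- Matrix::sparseMatrix(i = 1, j = 2, x = Inf, dims = c(3, 3))
  expect_error(encode_csr(s), "\\(1, 2\\)", class = "sch5_validation_error")
})

test_that("decode_csr expands known triplets and rejects invariant violations", {
  m <- decode_csr(sparse_triplet(5, 0, c(0, 0, 1), c(2, 2)))
  expect_equal(as.matrix(m), rbind(c(0, 0), c(5, 0)), ignore_attr = TRUE)

  e <- decode_csr(sparse_triplet(numeric(0), numeric(0), 0, c(0, 0)))
  expect_equal(dim(e), c(0L, 0L))

  expect_error(
    decode_csr(sparse_triplet(c(1, 2), c(0, 1), c(0, 2, 1), c(2, 2))),
    "indptr not nondecreasing",
    class = "sch5_validation_error"
  )
  expect_error(
    decode_csr(sparse_triplet(1, 5, c(0, 1), c(1, 3))),
    "column index out of range",
    class = "sch5_validation_error"
  )
})

test_that("encode/decode/transpose agree with the dense brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    nr <- sample(0:20, 1)
    nc <- sample(1:20, 1)
    density <- sample(c(0, 0.1, 0.5, 0.9, 1), 1)
    m <- rand_mat(nr, nc, density)

    t <- encode_csr(m)
    o <- oracle_encode_csr(m)
    expect_equal(t$data, o$data)
    expect_equal(t$indices, o$indices)
    expect_equal(t$indptr, o$indptr)

    back <- as.matrix(decode_csr(t))
    expect_equal(back, oracle_decode_csr(o$data, o$indices, o$indptr, dim(m)),
      ignore_attr = TRUE
    )

    tt <- transpose_triplet(t)
    ot <- oracle_encode_csr(t(m))
    expect_equal(tt$data, ot$data)
    expect_equal(tt$indices, ot$indices)
    expect_equal(tt$indptr, ot$indptr)
    expect_equal(tt$shape, rev(t$shape))
  }
})

test_that("transpose is an involution and handles row vectors", {
  set.seed(7)
  for (rep in 1:20) {
    m <- rand_mat(sample(1:15, 1), sample(1:15, 1), runif(1))
    t <- encode_csr(m)
    expect_true(triplet_identical(transpose_triplet(transpose_triplet(t)), t))
  }
  rv <- encode_csr(matrix(c(1, 0, 2, 0), 1, 4))
  cv <- transpose_triplet(rv)
  expect_equal(cv$shape, c(4, 1))
  expect_length(cv$indptr, 5)
})

test_that("plan_blocks partitions rows into contiguous full blocks", {
  p <- plan_blocks(12003, 5000)
  expect_equal(nrow(p$spans), 3)
  expect_equal(unname(p$spans[, "start"]), c(0, 5000, 10000))
  expect_equal(unname(p$spans[, "end"]), c(5000, 10000, 12003))

  expect_equal(nrow(plan_blocks(5000, 5000)$spans), 1)
  expect_equal(nrow(plan_blocks(0)$spans), 0)
  expect_error(plan_blocks(10, 0), class = "sch5_parameter_error")

  # invariants over assorted sizes
  for (n in c(1, 7, 99, 100, 101, 12003)) {
    for (bs in c(1, 7, 100, 5000)) {
      sp <- plan_blocks(n, bs)$spans
      expect_equal(nrow(sp), ceiling(n / bs))
      expect_equal(sp[1, "start"], c(start = 0))
      expect_equal(sp[nrow(sp), "end"], c(end = n))
      lens <- sp[, "end"] - sp[, "start"]
      expect_true(all(lens <= bs))
      expect_true(all(lens[-length(lens)] == bs))
      if (nrow(sp) > 1) {
        expect_equal(unname(sp[-1, "start"]), unname(sp[-nrow(sp), "end"]))
      }
    }
  }
})

test_that("slice_rows extracts sub-triplets with local indptr", {
  t <- encode_csr(rbind(c(0, 1, 0), c(2, 0, 3)))
  s <- slice_rows(t, c(1, 2))
  expect_equal(s$data, c(2, 3))
  expect_equal(s$indices, c(0, 2))
  expect_equal(s$indptr, c(0, 2))
  expect_equal(s$shape, c(1, 3))

  expect_true(triplet_identical(slice_rows(t, c(0, 2)), t))

  z <- slice_rows(encode_csr(matrix(0, 4, 3)), c(1, 3))
  expect_length(z$data, 0)
  expect_equal(z$indptr, c(0, 0, 0))

  expect_error(slice_rows(t, c(1, 5)), class = "sch5_parameter_error")
})

test_that("concatenating block slices reproduces the triplet bit-for-bit", {
  set.seed(42)
  m <- rand_mat(103, 17, 0.3)
  t <- encode_csr(m)
  for (bs in c(1, 2, 7, 100, 5000)) {
    plan <- plan_blocks(nrow(m), bs)
    blocks <- lapply(seq_len(nrow(plan$spans)), function(b) {
      slice_rows(t, plan$spans[b, ])
    })
    expect_true(triplet_identical(concat_triplets(blocks), t))
    # nnz conservation and per-block indptr bound
    nnz <- vapply(blocks, function(b) length(b$data), double(1))
    expect_equal(sum(nnz), length(t$data))
    for (b in blocks) {
      expect_equal(max(b$indptr), length(b$data))
    }
  }
})

test_that("index width switches exactly at the 32-bit boundary", {
  expect_equal(select_index_width(2^31 - 1), "int32")
  expect_equal(select_index_width(2^31), "int64")
  expect_equal(select_index_width(0), "int32")
  # test seam: lowered threshold
  expect_equal(select_index_width(1000, int32_max = 1000), "int32")
  expect_equal(select_index_width(1001, int32_max = 1000), "int64")
  expect_error(select_index_width(-1), class = "sch5_parameter_error")
})
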