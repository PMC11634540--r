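#' Sparse CSR triplets and blocked row storage
#'
#' The on-disk representation of every expression layer and cell-cell graph
#' is a compressed-sparse-row (CSR) triplet: `data` holds the nonzero values,
#' `indices` the 0-based column index of each value, and `indptr` the 0-based
#' offset at which each row starts (`length(indptr) == n_rows + 1`).  Rows are
#' partitioned into fixed-size blocks (5000 cells by default) and each block
#' is written as an independent triplet, so that a block's `indptr` never
#' exceeds the block's own nonzero count.  This keeps every stored index
#' pointer within the signed 32-bit range that R's native integers impose,
#' even when the whole matrix holds more than 2^31 - 1 nonzeros.
#'
#' `sparse_triplet()` builds a triplet from its parts; `encode_csr()` and
#' `decode_csr()` convert between matrices and canonical triplets.
#'
#' Canonical form means: within each row column indices are strictly
#' increasing, there are no explicit zeros and no duplicate entries.
#'
#' @param data numeric vector of nonzero values.
#' @param indices integer-valued vector of 0-based column indices.
#' @param indptr integer-valued vector of row start offsets, length
#'   `n_rows + 1`, first element 0, nondecreasing.
#' @param shape length-2 vector `(n_rows, n_cols)`.
#' @return `sparse_triplet()` returns an object of class `"sparse_triplet"`,
#'   a list with elements `data`, `indices`, `indptr` and `shape`.
#'   Index vectors are stored as doubles so values beyond the 32-bit range
#'   are representable in memory.
#' @seealso [encode_csr()], [decode_csr()], [plan_blocks()], [slice_rows()]
#' @export
sparse_triplet <- function(data, indices, indptr, shape) {
  structure(
    list(
      data = as.double(data),
      indices = as.double(indices),
      indptr = as.double(indptr),
      shape = as.double(shape)
    ),
    class = "sparse_triplet"
  )
}

#' @export
print.sparse_triplet <- function(x, ...) {
  cat(sprintf(
    "<sparse_triplet> %d x %d, %d stored values\n",
    x$shape[1], x$shape[2], length(x$data)
  ))
  invisible(x)
}

# Returns a character vector of violated triplet invariants (empty = valid).
# Checks are ordered so the most structural failure is reported first.
validate_triplet <- function(t) {
  v <- character()
  if (!inherits(t, "sparse_triplet")) {
    return("not a sparse_triplet")
  }
  if (length(t$shape) != 2 || any(t$shape < 0)) {
    return("shape must be two nonnegative integers")
  }
  n_rows <- t$shape[1]
  n_cols <- t$shape[2]
  if (length(t$indptr) != n_rows + 1) {
    return(sprintf(
      "indptr length %d != n_rows + 1 = %d",
      length(t$indptr), n_rows + 1
    ))
  }
  if (any(diff(t$indptr) < 0)) {
    v <- c(v, "indptr not nondecreasing")
  }
  if (t$indptr[1] != 0) {
    v <- c(v, "indptr does not start at 0")
  }
  nnz <- length(t$data)
  if (length(t$indices) != nnz || t$indptr[n_rows + 1] != nnz) {
    v <- c(v, sprintf(
      "indptr terminal / array length mismatch (data %d, indices %d, indptr end %g)",
      nnz, length(t$indices), t$indptr[n_rows + 1]
    ))
  }
  if (nnz > 0 && (min(t$indices) < 0 || max(t$indices) >= n_cols)) {
    v <- c(v, "column index out of range")
  }
  if (length(v) == 0 && nnz > 0) {
    # strictly increasing indices within each row (canonical form)
    row_of <- rep.int(seq_len(n_rows), diff(t$indptr))
    d <- diff(t$indices)
    same_row <- row_of[-1] == row_of[-nnz]
    if (nnz > 1 && any(same_row & d <= 0)) {
      v <- c(v, "column indices not strictly increasing within a row")
    }
  }
  v
}

# Locate the first non-finite entry of a matrix and describe it.
first_nonfinite <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    g <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    bad <- which(!is.finite(g@x))
    if (length(bad) == 0) {
      return(NULL)
    }
    k <- bad[1]
    col <- findInterval(k - 1, g@p[-1]) + 1
    row <- g@i[k] + 1
    sprintf("(%d, %d)", row, col)
  } else {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) == 0) {
      return(NULL)
    }
    sprintf("(%d, %d)", bad[1, 1], bad[1, 2])
  }
}

#' Encode a matrix as a canonical CSR triplet
#'
#' Explicit zeros are dropped and column indices are sorted within each row,
#' so `decode_csr(encode_csr(m))` reproduces `m` elementwise and two equal
#' matrices always produce identical triplets.
#'
#' @param m a base matrix or any `Matrix` sparse/dense matrix with finite
#'   values.
#' @return a [sparse_triplet()].
#' @examples
#' encode_csr(rbind(c(0, 1, 0), c(2, 0, 3)))
#' @export
encode_csr <- function(m) {
  if (length(dim(m)) != 2) {
    stop_validation("encode_csr: input must be a 2-D matrix")
  }
  bad <- first_nonfinite(m)
  if (!is.null(bad)) {
    stop_validation(sprintf("encode_csr: non-finite value at entry %s", bad))
  }
  if (inherits(m, "sparseMatrix")) {
    g <- Matrix::drop0(as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix"))
    r <- as(g, "RsparseMatrix")
  } else {
    mm <- as.matrix(m)
    storage.mode(mm) <- "double"
    r <- as(as(as(Matrix::Matrix(mm, sparse = TRUE), "dMatrix"), "generalMatrix"),
      "RsparseMatrix"
    )
  }
  sparse_triplet(r@x, r@j, r@p, dim(m))
}

#' Decode a CSR triplet into a sparse matrix
#'
#' @param t a [sparse_triplet()].  Invariants are checked; a violated rule is
#'   reported by name.
#' @return a `dgCMatrix` of shape `t$shape` (dense-equivalent to the encoded
#'   matrix).
#' @export
decode_csr <- function(t) {
  v <- validate_triplet(t)
  if (length(v) > 0) {
    stop_validation(paste0("decode_csr: ", v[1]))
  }
  r <- new("dgRMatrix",
    p = as.integer(t$indptr), j = as.integer(t$indices),
    x = as.double(t$data), Dim = as.integer(t$shape)
  )
  as(r, "CsparseMatrix")
}

#' Transpose a CSR triplet
#'
#' The result is the canonical CSR form of the transposed matrix — which is
#' exactly the column-compressed (CSC / `dgCMatrix`) form of the original.
#' This is the operation applied at the boundary with column-oriented
#' ecosystems (Seurat stores genes x cells `dgCMatrix`; this container is
#' row-compressed cells x genes).
#'
#' @inheritParams decode_csr
#' @return a [sparse_triplet()] with reversed shape and the same nonzeros.
#' @export
transpose_triplet <- function(t) {
  encode_csr(Matrix::t(decode_csr(t)))
}

#' Partition rows into fixed-size blocks
#'
#' Every matrix is stored as `ceiling(n_rows / block_size)` independent row
#' blocks; all blocks except possibly the last hold exactly `block_size`
#' rows.  The default of 5000 cells per block bounds each block's `indptr`
#' by the block's own nonzero count, keeping it far inside the 32-bit range.
#'
#' @param n_rows nonnegative number of rows (cells).
#' @param block_size positive block length in rows; default 5000.
#' @return an object of class `"block_plan"`: a list with `block_size` and
#'   `spans`, a matrix with columns `start`, `end` giving 0-based half-open
#'   row ranges.
#' @examples
#' plan_blocks(12003, 5000) # three spans: [0,5000), [5000,10000), [10000,12003)
#' @export
plan_blocks <- function(n_rows, block_size = 5000) {
  if (length(block_size) != 1 || is.na(block_size) || block_size < 1 ||
    block_size != floor(block_size)) {
    stop_parameter("plan_blocks: block_size must be a positive integer")
  }
  if (length(n_rows) != 1 || is.na(n_rows) || n_rows < 0) {
    stop_parameter("plan_blocks: n_rows must be a nonnegative integer")
  }
  n_rows <- as.double(n_rows)
  block_size <- as.double(block_size)
  n_blocks <- ceiling(n_rows / block_size)
  if (n_blocks == 0) {
    spans <- cbind(start = double(0), end = double(0))
  } else {
    start <- (seq_len(n_blocks) - 1) * block_size
    spans <- cbind(start = start, end = pmin(start + block_size, n_rows))
  }
  structure(list(block_size = block_size, spans = spans), class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf(
    "<block_plan> %d block(s) of size <= %g\n",
    nrow(x$spans), x$block_size
  ))
  invisible(x)
}

#' Extract a contiguous row range of a CSR triplet
#'
#' @inheritParams decode_csr
#' @param span length-2 vector `(start, end)`, a 0-based half-open row range
#'   (matching the `indptr` convention and [plan_blocks()] spans).
#' @return a [sparse_triplet()] for the selected rows, with a local `indptr`
#'   restarting at 0.  Concatenating the slices of a full block plan with
#'   [concat_triplets()] reproduces the original triplet exactly.
#' @export
slice_rows <- function(t, span) {
  v <- validate_triplet(t)
  if (length(v) > 0) {
    stop_validation(paste0("slice_rows: ", v[1]))
  }
  start <- span[1]
  end <- span[2]
  n_rows <- t$shape[1]
  if (length(span) != 2 || is.na(start) || is.na(end) ||
    start < 0 || end < start || end > n_rows) {
    stop_parameter(sprintf(
      "slice_rows: span [%s, %s) out of bounds for %g rows",
      format(start), format(end), n_rows
    ))
  }
  ptr <- t$indptr[(start + 1):(end + 1)]
  lo <- t$indptr[start + 1]
  hi <- t$indptr[end + 1]
  sel <- if (hi > lo) (lo + 1):hi else integer(0)
  sparse_triplet(t$data[sel], t$indices[sel], ptr - lo, c(end - start, t$shape[2]))
}

#' Concatenate row-block triplets back into one triplet
#'
#' @param blocks list of [sparse_triplet()]s with identical column counts,
#'   in row order.
#' @return a single [sparse_triplet()] stacking the blocks row-wise.
#' @export
concat_triplets <- function(blocks) {
  if (length(blocks) == 0) {
    stop_parameter("concat_triplets: need at least one block")
  }
  n_cols <- vapply(blocks, function(b) b$shape[2], double(1))
  if (length(unique(n_cols)) != 1) {
    stop_validation("concat_triplets: blocks disagree on column count")
  }
  data <- unlist(lapply(blocks, `[[`, "data"), use.names = FALSE)
  indices <- unlist(lapply(blocks, `[[`, "indices"), use.names = FALSE)
  indptr <- 0
  offset <- 0
  for (b in blocks) {
    if (length(b$indptr) > 1) {
      indptr <- c(indptr, b$indptr[-1] + offset)
    }
    offset <- offset + b$indptr[length(b$indptr)]
  }
  n_rows <- sum(vapply(blocks, function(b) b$shape[1], double(1)))
  sparse_triplet(
    if (is.null(data)) double(0) else data,
    if (is.null(indices)) double(0) else indices,
    indptr, c(n_rows, n_cols[1])
  )
}

#' Choose the integer width for an on-disk index array
#'
#' R's native integers are signed 32-bit, so any stored index array whose
#' maximum exceeds `2^31 - 1` must be written as 64-bit.  The width is chosen
#' per array from its actual maximum: `indices` are bounded by `n_cols - 1`,
#' `indptr` by the (per-block) nonzero count.
#'
#' @param max_index_value the largest value the array will hold.
#' @param int32_max the 32-bit boundary; the default is `2^31 - 1`.  Exposed
#'   as a test seam so overflow behaviour can be exercised on small inputs.
#' @return `"int32"` if `max_index_value <= int32_max`, else `"int64"`.
#' @export
select_index_width <- function(max_index_value, int32_max = .INT32_MAX) {
  if (length(max_index_value) != 1 || is.na(max_index_value) ||
    max_index_value < 0) {
    stop_parameter("select_index_width: max_index_value must be nonnegative")
  }
  if (max_index_value <= int32_max) "int32" else "int64"
}
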