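# Independent brute-force oracles for the sparse and factor codecs.
# Deliberately naive row/element scans with no shared code with the package.

oracle_encode_csr <- function(m) {
  m <- as.matrix(m)
  data <- numeric(0)
  indices <- numeric(0)
  indptr <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] != 0) {
        data <- c(data, m[i, j])
        indices <- c(indices, j - 1)
      }
    }
    indptr <- c(indptr, length(data))
  }
  list(data = data, indices = indices, indptr = indptr, shape = dim(m))
}

oracle_decode_csr <- function(data, indices, indptr, shape) {
  m <- matrix(0, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    ks <- seq_len(indptr[i + 1] - indptr[i]) + indptr[i]
    for (k in ks) {
      m[i, indices[k] + 1] <- data[k]
    }
  }
  m
}

oracle_encode_factor <- function(values) {
  categories <- character(0)
  codes <- integer(0)
  for (v in values) {
    if (is.na(v)) {
      codes <- c(codes, -1L)
    } else {
      if (!(v %in% categories)) categories <- c(categories, v)
      codes <- c(codes, match(v, categories) - 1L)
    }
  }
  list(categories = categories, codes = codes)
}

# Random dense test matrix with integer-ish values; density 0 and 1 legal.
rand_mat <- function(nr, nc, density) {
  keep <- stats::runif(nr * nc) < density
  vals <- round(stats::runif(nr * nc, 1, 9))
  matrix(ifelse(keep, vals, 0), nr, nc)
}

# Random annotation table over the five supported column kinds.
rand_table <- function(n_rows, n_cols, missing_rate = 0.2) {
  pool <- c("T", "B", "NK", "naïve-T", "γδ-T", "Mono")
  cols <- list()
  for (k in seq_len(n_cols)) {
    kind <- sample(c("numeric", "integer", "boolean", "string", "factor"), 1)
    x <- switch(kind,
      numeric = {
        v <- stats::rnorm(n_rows)
        v[stats::runif(n_rows) < missing_rate] <- NA
        v
      },
      integer = sample.int(100L, n_rows, replace = TRUE),
      boolean = sample(c(TRUE, FALSE), n_rows, replace = TRUE),
      string = sample(pool, n_rows, replace = TRUE),
      factor = {
        v <- sample(pool, n_rows, replace = TRUE)
        v[stats::runif(n_rows) < missing_rate] <- NA
        factor(v, levels = sample(pool)) # includes unused levels
      }
    )
    cols[[paste0("col", k, "_", kind)]] <- x
  }
  if (n_cols == 0) {
    data.frame(row.names = sprintf("r%04d", seq_len(n_rows)))
  } else {
    data.frame(cols, row.names = sprintf("r%04d", seq_len(n_rows)), check.names = FALSE)
  }
}

triplet_identical <- function(a, b) {
  identical(a$data, b$data) && identical(a$indices, b$indices) &&
    identical(a$indptr, b$indptr) && identical(a$shape, b$shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

local_h5 <- function(x, ..., envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".h5", .local_envir = envir)
  write_h5(x, path, ...)
  path
}
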