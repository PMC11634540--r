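#' Categorical (factor) column encoding
#'
#' On disk, a factor column is a pair of datasets: `categories`, the ordered
#' unique level strings, and `codes`, a 0-based integer per row referencing a
#' category (`-1` marks a missing value).  Category order is the order of
#' first appearance for plain character input, or the level order for factor
#' input — it is never re-sorted, so user-intended level order survives the
#' round trip, as do unused levels.
#'
#' @param values a character vector (possibly with `NA`) or a factor.
#' @return `encode_factor()` returns an object of class `"factor_column"`:
#'   a list with `categories` (character) and `codes` (integer, 0-based,
#'   `-1` = missing).
#' @examples
#' encode_factor(c("T", "B", "T", "NK"))
#' decode_factor(factor_column(c("A", "B"), c(1L, 0L)))
#' @export
encode_factor <- function(values) {
  if (is.factor(values)) {
    categories <- levels(values)
    codes <- as.integer(values) - 1L
  } else {
    values <- as.character(values)
    categories <- unique(values[!is.na(values)])
    codes <- match(values, categories) - 1L
  }
  codes[is.na(codes)] <- -1L
  factor_column(categories, codes)
}

#' @param categories ordered unique level strings.
#' @param codes integer vector of 0-based category references; `-1` = missing.
#' @rdname encode_factor
#' @export
factor_column <- function(categories, codes) {
  structure(
    list(categories = as.character(categories), codes = as.integer(codes)),
    class = "factor_column"
  )
}

#' @export
print.factor_column <- function(x, ...) {
  cat(sprintf(
    "<factor_column> %d values, %d categories: %s\n",
    length(x$codes), length(x$categories),
    paste(utils::head(x$categories, 5), collapse = ", ")
  ))
  invisible(x)
}

# Violated factor_column invariants as a character vector (empty = valid).
validate_factor_column <- function(f) {
  v <- character()
  if (anyDuplicated(f$categories)) {
    v <- c(v, "categories contain duplicates")
  }
  if (anyNA(f$categories)) {
    v <- c(v, "categories contain missing values")
  }
  bad <- which(f$codes < -1 | f$codes >= length(f$categories))
  if (length(bad) > 0) {
    v <- c(v, sprintf("code out of range at row %d", bad[1]))
  }
  v
}

#' @param f a `factor_column`.
#' @return `decode_factor()` returns an R `factor` whose levels are the
#'   stored categories (order and unused levels preserved); missing codes
#'   decode to `NA`.  `as.character()` of the result recovers the original
#'   string-or-missing vector.
#' @rdname encode_factor
#' @export
decode_factor <- function(f) {
  v <- validate_factor_column(f)
  if (length(v) > 0) {
    stop_validation(paste0("decode_factor: ", v[1]))
  }
  codes <- f$codes
  codes[codes == -1L] <- NA_integer_
  structure(codes + 1L, levels = f$categories, class = "factor")
}

# Column kind detection ------------------------------------------------------

column_kind <- function(x) {
  if (is.factor(x)) {
    "factor"
  } else if (is.logical(x)) {
    "boolean"
  } else if (is.integer(x)) {
    "integer"
  } else if (is.double(x)) {
    "numeric"
  } else if (is.character(x)) {
    "string"
  } else {
    NA_character_
  }
}

.TABLE_KINDS <- c("numeric", "integer", "boolean", "string", "factor")

#' Write / read an annotation table
#'
#' Cell (`obs`) and gene (`var`) annotation tables are stored one column per
#' dataset under the group, each carrying a `kind` attribute
#' (`numeric`, `integer`, `boolean`, `string` or `factor`).  Factor columns
#' are subgroups holding `categories` and `codes` datasets.  Row names go to
#' an `_index` dataset and column order to a `column_order` group attribute,
#' so insertion order survives HDF5's alphabetical listing.
#'
#' Missing values are supported in numeric columns (stored as-is; R's `NA`
#' is a NaN payload that round-trips bit-exact) and in factor columns
#' (code `-1`).  Integer, boolean and plain string columns must be complete:
#' use a factor for strings-with-missing or a numeric column for
#' integers-with-missing.
#'
#' @param t a `data.frame` with row names; columns of the five supported
#'   kinds.
#' @param loc an HDF5 file path or open file handle.
#' @param group_name group to write into / read from (e.g. `"obs"`, `"var"`).
#' @return `read_table()` returns the `data.frame` back, equal to what was
#'   written: row names, column order, kinds, values, and factor categories
#'   (order and unused levels included).
#' @export
write_table <- function(t, loc, group_name) {
  if (!is.data.frame(t)) {
    stop_parameter("write_table: t must be a data.frame")
  }
  cols <- names(t)
  if (anyDuplicated(cols) || any(cols == "") || any(grepl("/", cols, fixed = TRUE))) {
    stop_parameter("write_table: column names must be unique, nonempty and '/'-free")
  }
  # validate every column up front so a refused table writes nothing at all
  for (nm in cols) {
    kind <- column_kind(t[[nm]])
    if (is.na(kind)) {
      stop_parameter(sprintf(
        "write_table: column '%s' has unsupported type '%s'",
        nm, class(t[[nm]])[1]
      ))
    }
    if (kind %in% c("integer", "boolean", "string") && anyNA(t[[nm]])) {
      stop_parameter(sprintf(
        "write_table: %s column '%s' contains missing values; use a factor or numeric column",
        kind, nm
      ))
    }
  }
  with_h5(loc, function(fid) {
    rhdf5::h5createGroup(fid, group_name)
    h5_write_vec(fid, paste0(group_name, "/_index"), rownames(t))
    if (length(cols) > 0) {
      h5_put_attr(fid, group_name, "column_order", cols)
    }
    for (nm in cols) {
      x <- t[[nm]]
      kind <- column_kind(x)
      path <- paste0(group_name, "/", nm)
      switch(kind,
        factor = {
          fc <- encode_factor(x)
          rhdf5::h5createGroup(fid, path)
          h5_write_vec(fid, paste0(path, "/categories"), fc$categories)
          h5_write_vec(fid, paste0(path, "/codes"), fc$codes)
        },
        boolean = h5_write_vec(fid, path, as.integer(x), h5type = "H5T_STD_I8LE"),
        numeric = h5_write_vec(fid, path, as.double(x)),
        integer = h5_write_vec(fid, path, x),
        string = h5_write_vec(fid, path, x)
      )
      h5_put_attr(fid, path, "kind", kind)
    }
  })
  invisible(NULL)
}

#' @rdname write_table
#' @export
read_table <- function(loc, group_name) {
  with_h5(loc, function(fid) {
    if (!rhdf5::H5Lexists(fid, group_name)) {
      stop_schema(sprintf("read_table: missing group /%s", group_name))
    }
    if (!rhdf5::H5Lexists(fid, paste0(group_name, "/_index"))) {
      stop_schema(sprintf("read_table: missing dataset /%s/_index", group_name))
    }
    idx <- as.character(h5_read(fid, paste0(group_name, "/_index")))
    ga <- h5_attrs(fid, group_name)
    cols <- if (is.null(ga$column_order)) character(0) else as.character(ga$column_order)
    out <- vector("list", length(cols))
    names(out) <- cols
    for (nm in cols) {
      path <- paste0(group_name, "/", nm)
      if (!rhdf5::H5Lexists(fid, path)) {
        stop_schema(sprintf("read_table: missing column /%s", path))
      }
      kind <- h5_attrs(fid, path)$kind
      if (is.null(kind) || !(kind %in% .TABLE_KINDS)) {
        stop_schema(sprintf(
          "read_table: column /%s has unknown kind marker '%s'",
          path, if (is.null(kind)) "<absent>" else kind
        ))
      }
      x <- switch(kind,
        factor = decode_factor(factor_column(
          as.character(h5_read(fid, paste0(path, "/categories"))),
          as.integer(h5_read(fid, paste0(path, "/codes")))
        )),
        boolean = as.logical(h5_read(fid, path)),
        numeric = as.double(h5_read(fid, path)),
        integer = as.integer(h5_read(fid, path)),
        string = as.character(h5_read(fid, path))
      )
      if (length(x) != length(idx)) {
        stop_validation(sprintf(
          "read_table: column /%s has %d values for %d rows",
          path, length(x), length(idx)
        ))
      }
      out[[nm]] <- x
    }
    df <- if (length(cols) == 0) {
      data.frame(row.names = idx)
    } else {
      data.frame(out, row.names = idx, check.names = FALSE)
    }
    df
  })
}
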