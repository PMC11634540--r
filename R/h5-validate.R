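#' Validate a .h5 file against the container schema
#'
#' Walks the whole file and checks structure and content: presence of the
#' root name datasets and groups, matrix-group attributes and shapes,
#' per-block CSR invariants (`indptr` monotonicity, index ranges, nonzero
#' conservation), annotation-table kind markers and factor code ranges,
#' name/table alignment, embedding and graph shapes, and spatial image /
#' coordinate / scale-factor consistency.  Content problems are reported,
#' never raised; only a file that is not HDF5 at all is a hard error.
#'
#' Checks whose premises are broken are skipped rather than cascaded: a
#' missing `names_obs` suppresses every check that needs the cell count, a
#' non-square graph suppresses that graph's block checks, a wrong-channel
#' image suppresses the in-bounds coordinate check.  Each defect therefore
#' surfaces as exactly one violation.
#'
#' @param path path to an HDF5 file.
#' @return a `data.frame` with columns `path`, `rule`, `message`; zero rows
#'   means the file conforms, and [read_h5()] succeeds exactly when this is
#'   empty.
#' @export
validate_h5 <- function(path) {
  if (!file.exists(path)) {
    stop_io(sprintf("validate_h5: no such file '%s'", path))
  }
  if (!isTRUE(rhdf5::H5Fis_hdf5(path))) {
    stop_io(sprintf("validate_h5: '%s' is not an HDF5 file", path))
  }
  viol <- list()
  add <- function(p, rule, msg) {
    viol[[length(viol) + 1]] <<- data.frame(
      path = p, rule = rule, message = msg, stringsAsFactors = FALSE
    )
  }

  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  ls_df <- rhdf5::h5ls(fid)

  read_names <- function(nm) {
    if (!rhdf5::H5Lexists(fid, nm)) {
      add(paste0("/", nm), "missing_dataset", sprintf("missing /%s", nm))
      return(NULL)
    }
    x <- as.character(h5_read(fid, nm))
    if (anyDuplicated(x)) {
      add(paste0("/", nm), "duplicate_names", sprintf("/%s contains duplicates", nm))
    }
    if (any(x == "")) {
      add(paste0("/", nm), "empty_name", sprintf("/%s contains empty strings", nm))
    }
    x
  }
  names_obs <- read_names("names_obs")
  names_var <- read_names("names_var")
  n_cells <- if (is.null(names_obs)) NA_real_ else length(names_obs)
  n_genes <- if (is.null(names_var)) NA_real_ else length(names_var)

  for (g in c("assay", "obs", "var", "reductions", "graphs")) {
    if (!rhdf5::H5Lexists(fid, g)) {
      add(paste0("/", g), "missing_group", sprintf("missing group /%s", g))
    }
  }

  # --- matrix groups --------------------------------------------------------
  # expected_shape entries may be NA (unknown premise): NA disables that
  # dimension's comparison.  square = TRUE enforces shape[1] == shape[2]
  # (graphs) with the single rule "graph_not_square".
  check_matrix_group <- function(name, expected_shape, square = FALSE) {
    p <- paste0("/", name)
    at <- h5_attrs(fid, name)
    if (is.null(at$encoding) || !(at$encoding %in% c("csr_blocked", "dense"))) {
      add(p, "unknown_encoding", sprintf(
        "encoding attribute missing or unknown ('%s')",
        if (is.null(at$encoding)) "<absent>" else at$encoding
      ))
      return(invisible(NULL))
    }
    if (is.null(at$shape) || length(at$shape) != 2) {
      add(p, "missing_shape", "shape attribute missing or malformed")
      return(invisible(NULL))
    }
    shape <- as.double(at$shape)
    if (square) {
      if (shape[1] != shape[2] ||
        (!is.na(expected_shape[1]) && shape[1] != expected_shape[1])) {
        add(p, "graph_not_square", sprintf(
          "graph has shape (%g, %g), expected (%s, %s)",
          shape[1], shape[2], format(expected_shape[1]), format(expected_shape[1])
        ))
        return(invisible(NULL))
      }
    } else {
      mism <- (!is.na(expected_shape[1]) && shape[1] != expected_shape[1]) ||
        (!is.na(expected_shape[2]) && shape[2] != expected_shape[2])
      if (mism) {
        add(p, "shape_mismatch", sprintf(
          "declared shape (%g, %g) disagrees with names (%s, %s)",
          shape[1], shape[2], format(expected_shape[1]), format(expected_shape[2])
        ))
        return(invisible(NULL))
      }
    }
    if (at$encoding == "dense") {
      dn <- paste0(name, "/dense")
      if (!rhdf5::H5Lexists(fid, dn)) {
        add(p, "missing_dataset", sprintf("missing /%s", dn))
        return(invisible(NULL))
      }
      d <- ls_df[ls_df$group == p & ls_df$name == "dense", "dim"]
      dims <- as.double(strsplit(d, " x ", fixed = TRUE)[[1]])
      if (length(dims) != 2 || any(dims != shape)) {
        add(p, "shape_mismatch", "dense dataset dims disagree with shape attribute")
      }
      return(invisible(NULL))
    }
    n_blocks <- as.double(at$n_blocks)
    block_size <- as.double(at$block_size)
    if (length(n_blocks) != 1 || length(block_size) != 1 || is.na(n_blocks) ||
      is.na(block_size) || block_size < 1) {
      add(p, "missing_block_attrs", "block_size / n_blocks attributes missing or malformed")
      return(invisible(NULL))
    }
    if (n_blocks != ceiling(shape[1] / block_size)) {
      add(p, "block_count", sprintf(
        "n_blocks = %g but ceiling(%g / %g) = %g",
        n_blocks, shape[1], block_size, ceiling(shape[1] / block_size)
      ))
      return(invisible(NULL))
    }
    rows_seen <- 0
    for (bn in block_names(n_blocks)) {
      bp <- paste0(name, "/", bn)
      missing <- !vapply(
        paste0(bp, "/", c("data", "indices", "indptr")),
        function(nm) rhdf5::H5Lexists(fid, nm), logical(1)
      )
      if (any(missing)) {
        add(paste0("/", bp), "missing_dataset", sprintf(
          "block missing %s",
          paste(c("data", "indices", "indptr")[missing], collapse = ", ")
        ))
        next
      }
      indptr <- as.double(h5_read(fid, paste0(bp, "/indptr")))
      nd <- length(h5_read(fid, paste0(bp, "/data")))
      idx <- as.double(h5_read(fid, paste0(bp, "/indices")))
      rows_seen <- rows_seen + length(indptr) - 1
      # report at most one violation per block, most structural first
      if (length(indptr) < 1) {
        add(paste0("/", bp, "/indptr"), "indptr_empty", "indptr has no elements")
      } else if (any(diff(indptr) < 0)) {
        add(paste0("/", bp, "/indptr"), "indptr_not_nondecreasing", "indptr is not nondecreasing")
      } else if (indptr[1] != 0) {
        add(paste0("/", bp, "/indptr"), "indptr_start", "indptr does not start at 0")
      } else if (indptr[length(indptr)] != nd || length(idx) != nd) {
        add(paste0("/", bp, "/indptr"), "nnz_mismatch", sprintf(
          "indptr terminal %g != data length %d or indices length %d",
          indptr[length(indptr)], nd, length(idx)
        ))
      } else if (nd > 0 && (min(idx) < 0 || max(idx) >= shape[2])) {
        add(paste0("/", bp, "/indices"), "index_out_of_range", sprintf(
          "column indices outside [0, %g)", shape[2]
        ))
      }
    }
    if (rows_seen != shape[1]) {
      add(p, "block_rows", sprintf(
        "blocks cover %g rows but shape declares %g", rows_seen, shape[1]
      ))
    }
    invisible(NULL)
  }

  if (rhdf5::H5Lexists(fid, "assay")) {
    for (an in h5_children(ls_df, "/assay")) {
      for (ln in h5_children(ls_df, paste0("/assay/", an))) {
        check_matrix_group(paste0("assay/", an, "/", ln), c(n_cells, n_genes))
      }
    }
  }
  if (rhdf5::H5Lexists(fid, "graphs")) {
    for (gn in h5_children(ls_df, "/graphs")) {
      check_matrix_group(paste0("graphs/", gn), c(n_cells, n_cells), square = TRUE)
    }
  }

  # --- annotation tables ----------------------------------------------------
  check_table <- function(group_name, expected_names, what) {
    if (!rhdf5::H5Lexists(fid, group_name)) {
      return(invisible(NULL))
    }
    p <- paste0("/", group_name)
    if (!rhdf5::H5Lexists(fid, paste0(group_name, "/_index"))) {
      add(paste0(p, "/_index"), "missing_dataset", sprintf("missing %s/_index", p))
      return(invisible(NULL))
    }
    idx <- as.character(h5_read(fid, paste0(group_name, "/_index")))
    if (!is.null(expected_names) && !identical(idx, expected_names)) {
      add(paste0(p, "/_index"), "names_mismatch", sprintf(
        "%s/_index disagrees with /names_%s", p, what
      ))
    }
    n <- length(idx)
    cols <- setdiff(h5_children(ls_df, p), "_index")
    for (nm in cols) {
      cp <- paste0(group_name, "/", nm)
      kind <- h5_attrs(fid, cp)$kind
      if (is.null(kind) || !(kind %in% .TABLE_KINDS)) {
        add(paste0("/", cp), "unknown_kind", sprintf(
          "column kind marker missing or unknown ('%s')",
          if (is.null(kind)) "<absent>" else kind
        ))
        next
      }
      if (kind == "factor") {
        if (!rhdf5::H5Lexists(fid, paste0(cp, "/categories")) ||
          !rhdf5::H5Lexists(fid, paste0(cp, "/codes"))) {
          add(paste0("/", cp), "missing_dataset", "factor column missing categories/codes")
          next
        }
        cats <- as.character(h5_read(fid, paste0(cp, "/categories")))
        codes <- as.double(h5_read(fid, paste0(cp, "/codes")))
        if (anyDuplicated(cats)) {
          add(paste0("/", cp), "duplicate_categories", "factor categories contain duplicates")
        } else if (length(codes) > 0 && (min(codes) < -1 || max(codes) >= length(cats))) {
          bad <- which(codes < -1 | codes >= length(cats))[1]
          add(paste0("/", cp, "/codes"), "factor_code_out_of_range", sprintf(
            "code %g at row %d outside [-1, %d)", codes[bad], bad, length(cats)
          ))
        }
        nv <- length(codes)
      } else {
        nv <- as.double(strsplit(
          ls_df[ls_df$group == p & ls_df$name == nm, "dim"], " x ",
          fixed = TRUE
        )[[1]])[1]
      }
      if (!is.na(nv) && nv != n) {
        add(paste0("/", cp), "column_length", sprintf(
          "column has %g values for %d rows", nv, n
        ))
      }
    }
    invisible(NULL)
  }
  check_table("obs", names_obs, "obs")
  check_table("var", names_var, "var")

  # --- reductions -----------------------------------------------------------
  if (rhdf5::H5Lexists(fid, "reductions")) {
    for (rn in h5_children(ls_df, "/reductions")) {
      d <- ls_df[ls_df$group == "/reductions" & ls_df$name == rn, "dim"]
      dims <- as.double(strsplit(d, " x ", fixed = TRUE)[[1]])
      if (length(dims) != 2 || dims[2] < 1) {
        add(paste0("/reductions/", rn), "embedding_dims", "embedding must be 2-D with >= 1 dimension")
      } else if (!is.na(n_cells) && dims[1] != n_cells) {
        add(paste0("/reductions/", rn), "embedding_rows", sprintf(
          "embedding has %g rows for %g cells", dims[1], n_cells
        ))
      }
    }
  }

  # --- images ---------------------------------------------------------------
  if (rhdf5::H5Lexists(fid, "images")) {
    for (sn in h5_children(ls_df, "/images")) {
      base <- paste0("images/", sn)
      bp <- paste0("/", base)
      if (!rhdf5::H5Lexists(fid, paste0(base, "/image"))) {
        add(paste0(bp, "/image"), "missing_dataset", "missing spatial image")
      } else {
        d <- ls_df[ls_df$group == bp & ls_df$name == "image", "dim"]
        dims <- as.double(strsplit(d, " x ", fixed = TRUE)[[1]])
        if (length(dims) != 3 || dims[3] != 3) {
          add(paste0(bp, "/image"), "image_channels", sprintf(
            "image must have 3 channels, got dims (%s)", paste(dims, collapse = ", ")
          ))
        }
      }
      if (!rhdf5::H5Lexists(fid, paste0(base, "/coords"))) {
        add(paste0(bp, "/coords"), "missing_dataset", "missing spot coordinates")
      } else {
        d <- ls_df[ls_df$group == bp & ls_df$name == "coords", "dim"]
        dims <- as.double(strsplit(d, " x ", fixed = TRUE)[[1]])
        if (length(dims) != 2 || dims[2] != 2) {
          add(paste0(bp, "/coords"), "coords_shape", "coords must be n_spots x 2")
        } else if (!is.na(n_cells) && dims[1] != n_cells) {
          add(paste0(bp, "/coords"), "coords_count_mismatch", sprintf(
            "%g spot coordinates for %g cells", dims[1], n_cells
          ))
        }
      }
      if (!rhdf5::H5Lexists(fid, paste0(base, "/scale_factors"))) {
        add(paste0(bp, "/scale_factors"), "missing_group", "missing scale_factors group")
      } else {
        sf_names <- h5_children(ls_df, paste0(bp, "/scale_factors"))
        miss <- setdiff(.REQUIRED_SCALE_FACTORS, sf_names)
        if (length(miss) > 0) {
          add(paste0(bp, "/scale_factors"), "scale_factor_missing", sprintf(
            "missing scale factor(s): %s", paste(miss, collapse = ", ")
          ))
        }
        for (nm in sf_names) {
          val <- as.double(h5_read(fid, paste0(base, "/scale_factors/", nm)))
          if (length(val) != 1 || !is.finite(val) || val <= 0) {
            add(paste0(bp, "/scale_factors/", nm), "scale_factor_positive",
              "scale factor must be a finite positive scalar")
          }
        }
      }
    }
  }

  if (length(viol) == 0) no_file_violations() else do.call(rbind, viol)
}

no_file_violations <- function() {
  data.frame(
    path = character(0), rule = character(0), message = character(0),
    stringsAsFactors = FALSE
  )
}

#' Summarize the contents of a .h5 file
#'
#' @param path path to a conforming file (validated first; a nonconforming
#'   file is a schema error).
#' @return an object of class `"sch5_description"`: a list with `n_cells`,
#'   `n_genes`, `format_version`, per-assay layer summaries (encoding and
#'   nonzero count), reductions with dimensions, graphs with nonzero counts,
#'   and spatial sample names.
#' @export
describe_h5 <- function(path) {
  v <- validate_h5(path)
  if (nrow(v) > 0) {
    stop_schema(
      sprintf(
        "describe_h5: '%s' does not conform (%d violation(s); see validate_h5())",
        path, nrow(v)
      ),
      violations = v
    )
  }
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  ls_df <- rhdf5::h5ls(fid)

  matrix_summary <- function(name) {
    at <- h5_attrs(fid, name)
    if (identical(at$encoding, "dense")) {
      shape <- as.double(at$shape)
      vals <- h5_read(fid, paste0(name, "/dense"))
      list(encoding = "dense", shape = shape, nnz = sum(vals != 0))
    } else {
      nnz <- 0
      for (bn in block_names(as.double(at$n_blocks))) {
        ip <- h5_read(fid, paste0(name, "/", bn, "/indptr"))
        nnz <- nnz + as.double(ip[length(ip)])
      }
      list(encoding = "csr_blocked", shape = as.double(at$shape), nnz = nnz)
    }
  }

  assays <- list()
  for (an in h5_children(ls_df, "/assay")) {
    assays[[an]] <- lapply(
      stats::setNames(nm = h5_children(ls_df, paste0("/assay/", an))),
      function(ln) matrix_summary(paste0("assay/", an, "/", ln))
    )
  }
  reductions <- list()
  for (rn in h5_children(ls_df, "/reductions")) {
    d <- ls_df[ls_df$group == "/reductions" & ls_df$name == rn, "dim"]
    reductions[[rn]] <- as.double(strsplit(d, " x ", fixed = TRUE)[[1]])[2]
  }
  graphs <- lapply(
    stats::setNames(nm = h5_children(ls_df, "/graphs")),
    function(gn) matrix_summary(paste0("graphs/", gn))$nnz
  )
  spatial <- if (rhdf5::H5Lexists(fid, "images")) h5_children(ls_df, "/images") else character(0)

  structure(
    list(
      n_cells = length(h5_read(fid, "names_obs")),
      n_genes = length(h5_read(fid, "names_var")),
      format_version = h5_attrs(fid, "/")$format_version,
      assays = assays, reductions = reductions, graphs = graphs,
      spatial = spatial
    ),
    class = "sch5_description"
  )
}

#' @export
print.sch5_description <- function(x, ...) {
  cat(sprintf(
    "sch5 file: %d cells x %d genes (format %s)\n",
    x$n_cells, x$n_genes, x$format_version
  ))
  for (an in names(x$assays)) {
    for (ln in names(x$assays[[an]])) {
      s <- x$assays[[an]][[ln]]
      cat(sprintf(
        "  layer %s/%s: %s, %g nonzeros\n", an, ln, s$encoding, s$nnz
      ))
    }
  }
  for (rn in names(x$reductions)) {
    cat(sprintf("  reduction %s: %g dims\n", rn, x$reductions[[rn]]))
  }
  for (gn in names(x$graphs)) {
    cat(sprintf("  graph %s: %g nonzeros\n", gn, x$graphs[[gn]]))
  }
  if (length(x$spatial) > 0) {
    cat(sprintf("  spatial samples: %s\n", paste(x$spatial, collapse = ", ")))
  } else {
    cat("  spatial samples: none\n")
  }
  invisible(x)
}
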