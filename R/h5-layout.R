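#' Write a container to a unified .h5 file
#'
#' The file root holds two datasets, `names_obs` and `names_var` (cell and
#' gene names), and the groups `assay`, `obs`, `var`, `reductions` and
#' `graphs`; an `images` group is present only when the container carries
#' spatial data.  Expression layers live at `assay/<assay>/<layer>` and
#' graphs at `graphs/<name>`, each as a matrix group: either blocked CSR
#' (`block_00000`, `block_00001`, ... subgroups with `data` / `indices` /
#' `indptr` datasets, every block covering at most `block_size` cells) or a
#' single `dense` dataset.  Annotation tables are stored column-per-dataset
#' with the `categories`/`codes` factor encoding (see [write_table()]);
#' spatial samples as `images/<sample>/{image, coords, scale_factors}` (see
#' [spatial_block()]).
#'
#' Strings are variable-length UTF-8; index arrays are written 32-bit unless
#' their actual maximum exceeds the 32-bit boundary (see
#' [select_index_width()]); datasets are gzip-compressed.
#'
#' @param x a valid [sc_container()]; an invalid one is refused with the
#'   violation list in the error.
#' @param path output file path (overwritten if present).
#' @param block_size cells per CSR block; default 5000.
#' @param compression gzip level 0-9; default 4.
#' @param int32_max test seam for the 32-bit index boundary; leave at the
#'   default for real files.
#' @return `path`, invisibly.
#' @seealso [read_h5()], [validate_h5()], [describe_h5()]
#' @export
write_h5 <- function(x, path, block_size = 5000, compression = 4,
                     int32_max = .INT32_MAX) {
  if (!inherits(x, "sc_container")) {
    stop_parameter("write_h5: x must be an sc_container")
  }
  v <- validate_container(x)
  if (nrow(v) > 0) {
    stop_validation(
      paste0(
        "write_h5: refusing to write an invalid container:\n",
        paste(sprintf("  [%s] %s", v$rule, v$message), collapse = "\n")
      ),
      violations = v
    )
  }
  if (file.exists(path) && unlink(path) != 0) {
    stop_io(sprintf("write_h5: cannot overwrite '%s'", path))
  }
  fid <- tryCatch(rhdf5::H5Fcreate(path),
    error = function(e) stop_io(sprintf("write_h5: cannot create '%s': %s", path, conditionMessage(e)))
  )
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)

  h5_put_attr(fid, "/", "format_version", .SCH5_FORMAT_VERSION)
  h5_write_vec(fid, "names_obs", x$cell_names, level = compression)
  h5_write_vec(fid, "names_var", x$gene_names, level = compression)

  rhdf5::h5createGroup(fid, "assay")
  if (length(x$assays) > 0) {
    h5_put_attr(fid, "assay", "element_order", names(x$assays))
  }
  for (an in names(x$assays)) {
    rhdf5::h5createGroup(fid, paste0("assay/", an))
    layers <- x$assays[[an]]
    if (length(layers) > 0) {
      h5_put_attr(fid, paste0("assay/", an), "element_order", names(layers))
    }
    for (ln in names(layers)) {
      write_matrix_group(
        fid, paste0("assay/", an, "/", ln), layers[[ln]],
        block_size, compression, int32_max
      )
    }
  }

  write_table(x$obs, fid, "obs")
  write_table(x$var, fid, "var")

  rhdf5::h5createGroup(fid, "reductions")
  if (length(x$reductions) > 0) {
    h5_put_attr(fid, "reductions", "element_order", names(x$reductions))
  }
  for (rn in names(x$reductions)) {
    e <- x$reductions[[rn]]
    h5_write_array(fid, paste0("reductions/", rn), unname(e), level = compression)
    if (!is.null(colnames(e))) {
      h5_put_attr(fid, paste0("reductions/", rn), "dim_labels", colnames(e))
    }
  }

  rhdf5::h5createGroup(fid, "graphs")
  if (length(x$graphs) > 0) {
    h5_put_attr(fid, "graphs", "element_order", names(x$graphs))
  }
  for (gn in names(x$graphs)) {
    write_matrix_group(
      fid, paste0("graphs/", gn), x$graphs[[gn]],
      block_size, compression, int32_max
    )
  }

  if (!is.null(x$spatial) && length(x$spatial) > 0) {
    rhdf5::h5createGroup(fid, "images")
    h5_put_attr(fid, "images", "element_order", names(x$spatial))
    for (sn in names(x$spatial)) {
      write_spatial(fid, sn, x$spatial[[sn]], level = compression)
    }
  }
  invisible(path)
}

# Matrix group codec ---------------------------------------------------------

int_h5type <- function(width) {
  if (width == "int64") "H5T_STD_I64LE" else "H5T_STD_I32LE"
}

# Write one index array at the width its actual maximum requires.
write_index_vec <- function(fid, name, x, level, int32_max) {
  width <- select_index_width(if (length(x) > 0) max(x) else 0, int32_max)
  if (width == "int32") {
    h5_write_vec(fid, name, as.integer(x), level = level, h5type = "H5T_STD_I32LE")
  } else {
    h5_write_vec(fid, name, as.double(x), level = level, h5type = "H5T_STD_I64LE")
  }
}

write_matrix_group <- function(fid, name, m, block_size, level, int32_max) {
  rhdf5::h5createGroup(fid, name)
  if (!inherits(m, "sparseMatrix")) {
    h5_put_attr(fid, name, "encoding", "dense")
    h5_put_attr(fid, name, "shape", as.double(dim(m)))
    h5_write_array(fid, paste0(name, "/dense"), unname(m), level = level)
    return(invisible(NULL))
  }
  tr <- encode_csr(m)
  plan <- plan_blocks(nrow(m), block_size)
  h5_put_attr(fid, name, "encoding", "csr_blocked")
  h5_put_attr(fid, name, "shape", tr$shape)
  h5_put_attr(fid, name, "block_size", as.double(block_size))
  h5_put_attr(fid, name, "n_blocks", as.double(nrow(plan$spans)))
  for (b in seq_len(nrow(plan$spans))) {
    bt <- slice_rows(tr, plan$spans[b, ])
    grp <- sprintf("%s/block_%05d", name, b - 1)
    rhdf5::h5createGroup(fid, grp)
    h5_write_vec(fid, paste0(grp, "/data"), bt$data, level = level)
    write_index_vec(fid, paste0(grp, "/indices"), bt$indices, level, int32_max)
    write_index_vec(fid, paste0(grp, "/indptr"), bt$indptr, level, int32_max)
  }
  invisible(NULL)
}

block_names <- function(n_blocks) sprintf("block_%05d", seq_len(n_blocks) - 1)

read_matrix_group <- function(fid, name) {
  at <- h5_attrs(fid, name)
  enc <- at$encoding
  if (identical(enc, "dense")) {
    m <- h5_read(fid, paste0(name, "/dense"))
    storage.mode(m) <- "double"
    return(m)
  }
  shape <- as.double(at$shape)
  n_blocks <- as.double(at$n_blocks)
  blocks <- lapply(block_names(n_blocks), function(bn) {
    grp <- paste0(name, "/", bn)
    indptr <- as.double(h5_read(fid, paste0(grp, "/indptr")))
    sparse_triplet(
      as.double(h5_read(fid, paste0(grp, "/data"))),
      as.double(h5_read(fid, paste0(grp, "/indices"))),
      indptr,
      c(length(indptr) - 1, shape[2])
    )
  })
  tr <- if (n_blocks == 0) {
    sparse_triplet(double(0), double(0), rep(0, shape[1] + 1), shape)
  } else {
    concat_triplets(blocks)
  }
  decode_csr(tr)
}

#' Read a unified .h5 file into a container
#'
#' The file is validated first ([validate_h5()]); any schema or content
#' violation aborts the read with the violation list in the error message.
#' The returned container passes [validate_container()] and is the exact
#' inverse of [write_h5()] on every component.
#'
#' @param path path to a conforming `.h5` file.
#' @return an [sc_container()].
#' @export
read_h5 <- function(path) {
  v <- validate_h5(path)
  if (nrow(v) > 0) {
    stop_schema(
      paste0(
        sprintf("read_h5: '%s' does not conform to the schema:\n", path),
        paste(sprintf("  [%s] %s: %s", v$rule, v$path, v$message), collapse = "\n")
      ),
      violations = v
    )
  }
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  ls_df <- rhdf5::h5ls(fid)

  cell_names <- as.character(h5_read(fid, "names_obs"))
  gene_names <- as.character(h5_read(fid, "names_var"))

  ordered_children <- function(group) {
    kids <- h5_children(ls_df, group)
    ord <- h5_attrs(fid, sub("^/", "", group))$element_order
    if (!is.null(ord)) kids <- intersect(as.character(ord), kids)
    kids
  }

  assays <- list()
  for (an in ordered_children("/assay")) {
    layers <- list()
    for (ln in ordered_children(paste0("/assay/", an))) {
      layers[[ln]] <- read_matrix_group(fid, paste0("assay/", an, "/", ln))
    }
    assays[[an]] <- layers
  }

  obs <- read_table(fid, "obs")
  var <- read_table(fid, "var")

  reductions <- list()
  for (rn in ordered_children("/reductions")) {
    e <- h5_read(fid, paste0("reductions/", rn))
    storage.mode(e) <- "double"
    labels <- h5_attrs(fid, paste0("reductions/", rn))$dim_labels
    if (!is.null(labels)) colnames(e) <- as.character(labels)
    reductions[[rn]] <- e
  }

  graphs <- list()
  for (gn in ordered_children("/graphs")) {
    graphs[[gn]] <- read_matrix_group(fid, paste0("graphs/", gn))
  }

  spatial <- NULL
  if (rhdf5::H5Lexists(fid, "images")) {
    spatial <- list()
    for (sn in ordered_children("/images")) {
      spatial[[sn]] <- read_spatial(fid, sn)
    }
  }

  sc_container(
    assays = assays, obs = obs, var = var,
    reductions = reductions, graphs = graphs, spatial = spatial,
    cell_names = cell_names, gene_names = gene_names
  )
}
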