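#' In-memory single-cell container
#'
#' The canonical in-memory model behind the `.h5` schema.  Orientation is
#' cells x genes (rows = cells) throughout, matching the row-compressed
#' on-disk layout; column-oriented ecosystems (Seurat's genes x cells
#' `dgCMatrix`) are transposed at the adapter boundary, never inside the
#' model.
#'
#' Components:
#' * `cell_names`, `gene_names` — ordered, unique, nonempty strings.
#' * `assays` — named list of assays; each assay a named list of layer
#'   matrices (`n_cells x n_genes`), sparse (`dgCMatrix`) or dense.
#' * `obs`, `var` — `data.frame` annotation tables over cells / genes.
#' * `reductions` — named list of dense embedding matrices
#'   (`n_cells x n_dims`); column names, when present, are the dimension
#'   labels.
#' * `graphs` — named list of square sparse cell-cell matrices with
#'   nonnegative finite weights (nearest-neighbor `nn`, shared-nearest-
#'   neighbor `snn`, ...).
#' * `spatial` — optional named list of [spatial_block()]s, one per sample.
#'
#' The constructor assembles and normalizes (sparse layers are coerced to
#' `dgCMatrix`, dimnames are aligned to the name vectors) but does not
#' reject inconsistent input — use [validate_container()] to obtain the
#' list of violated invariants; [write_h5()] refuses to serialize an
#' invalid container.
#'
#' @param counts convenience shortcut: a single cells x genes counts matrix,
#'   equivalent to `assays = list(RNA = list(counts = counts))`.
#' @param assays named list of named lists of layer matrices.
#' @param obs,var annotation `data.frame`s (row names = cell / gene names).
#' @param reductions named list of embedding matrices.
#' @param graphs named list of square sparse matrices.
#' @param spatial `NULL` or named list of [spatial_block()]s.
#' @param cell_names,gene_names explicit name vectors; when omitted they are
#'   taken from the first layer's dimnames or the table row names.
#' @return an object of class `"sc_container"`.
#' @examples
#' m <- Matrix::rsparsematrix(10, 5, 0.3, rand.x = function(n) rpois(n, 2) + 1)
#' dimnames(m) <- list(paste0("cell-", 1:10), paste0("gene-", 1:5))
#' x <- sc_container(counts = m)
#' validate_container(x)
#' @export
sc_container <- function(counts = NULL, assays = NULL, obs = NULL, var = NULL,
                         reductions = list(), graphs = list(), spatial = NULL,
                         cell_names = NULL, gene_names = NULL) {
  if (!is.null(counts)) {
    if (!is.null(assays)) {
      stop_parameter("sc_container: give either counts or assays, not both")
    }
    assays <- list(RNA = list(counts = counts))
  }
  if (is.null(assays)) assays <- list()

  first_layer <- NULL
  for (a in assays) {
    if (length(a) > 0) {
      first_layer <- a[[1]]
      break
    }
  }
  if (is.null(cell_names)) {
    cell_names <- if (!is.null(obs)) {
      rownames(obs)
    } else if (!is.null(first_layer)) {
      rownames(first_layer)
    }
  }
  if (is.null(gene_names)) {
    gene_names <- if (!is.null(var)) {
      rownames(var)
    } else if (!is.null(first_layer)) {
      colnames(first_layer)
    }
  }
  if (is.null(cell_names) || is.null(gene_names)) {
    stop_parameter("sc_container: cell and gene names must be supplied or derivable")
  }
  cell_names <- as.character(cell_names)
  gene_names <- as.character(gene_names)

  norm_layer <- function(m) {
    if (inherits(m, "sparseMatrix")) {
      m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    } else {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
    }
    if (all(dim(m) == c(length(cell_names), length(gene_names)))) {
      dimnames(m) <- list(cell_names, gene_names)
    }
    m
  }
  assays <- lapply(assays, function(a) lapply(a, norm_layer))

  norm_graph <- function(g) {
    g <- as(as(as(g, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (all(dim(g) == length(cell_names))) {
      dimnames(g) <- list(cell_names, cell_names)
    }
    g
  }
  graphs <- lapply(graphs, norm_graph)

  norm_red <- function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (nrow(r) == length(cell_names)) rownames(r) <- cell_names
    r
  }
  reductions <- lapply(reductions, norm_red)

  if (is.null(obs)) obs <- data.frame(row.names = cell_names)
  if (is.null(var)) var <- data.frame(row.names = gene_names)

  structure(
    list(
      cell_names = cell_names, gene_names = gene_names,
      assays = assays, obs = obs, var = var,
      reductions = reductions, graphs = graphs, spatial = spatial
    ),
    class = "sc_container"
  )
}

#' @export
print.sc_container <- function(x, ...) {
  cat(sprintf(
    "<sc_container> %d cells x %d genes\n",
    length(x$cell_names), length(x$gene_names)
  ))
  for (a in names(x$assays)) {
    cat(sprintf("  assay %s: layers %s\n", a, paste(names(x$assays[[a]]), collapse = ", ")))
  }
  cat(sprintf("  obs: %d column(s); var: %d column(s)\n", ncol(x$obs), ncol(x$var)))
  if (length(x$reductions) > 0) {
    dims <- vapply(x$reductions, ncol, integer(1))
    cat(sprintf(
      "  reductions: %s\n",
      paste(sprintf("%s (%dd)", names(x$reductions), dims), collapse = ", ")
    ))
  }
  if (length(x$graphs) > 0) {
    cat(sprintf("  graphs: %s\n", paste(names(x$graphs), collapse = ", ")))
  }
  if (!is.null(x$spatial)) {
    cat(sprintf("  spatial samples: %s\n", paste(names(x$spatial), collapse = ", ")))
  }
  invisible(x)
}

violation <- function(component, rule, message) {
  data.frame(
    component = component, rule = rule, message = message,
    stringsAsFactors = FALSE
  )
}

no_violations <- function() {
  data.frame(
    component = character(0), rule = character(0), message = character(0),
    stringsAsFactors = FALSE
  )
}

check_names_vector <- function(nm, what) {
  v <- no_violations()
  if (anyNA(nm) || any(nm == "")) {
    v <- rbind(v, violation(what, "empty_name", sprintf("%s contain empty strings", what)))
  }
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    v <- rbind(v, violation(
      what, "duplicate_names",
      sprintf("duplicate %s: '%s'", what, dup[1])
    ))
  }
  v
}

#' Check a container against the model invariants
#'
#' Violations are data, not exceptions: each violated invariant yields one
#' record naming the component and the rule.  A valid container returns a
#' zero-row data frame.  The check is side-effect free and idempotent.
#'
#' @param x an [sc_container()].
#' @return a `data.frame` with columns `component`, `rule`, `message`;
#'   zero rows means valid.
#' @export
validate_container <- function(x) {
  if (!inherits(x, "sc_container")) {
    stop_parameter("validate_container: not an sc_container")
  }
  n_cells <- length(x$cell_names)
  n_genes <- length(x$gene_names)
  v <- rbind(
    check_names_vector(x$cell_names, "cell_names"),
    check_names_vector(x$gene_names, "gene_names")
  )

  for (a in names(x$assays)) {
    for (l in names(x$assays[[a]])) {
      m <- x$assays[[a]][[l]]
      if (!all(dim(m) == c(n_cells, n_genes))) {
        v <- rbind(v, violation(
          sprintf("assay %s/%s", a, l), "layer_shape",
          sprintf(
            "layer is %d x %d but container is %d cells x %d genes",
            nrow(m), ncol(m), n_cells, n_genes
          )
        ))
      }
    }
  }

  for (tb in c("obs", "var")) {
    expected <- if (tb == "obs") x$cell_names else x$gene_names
    t <- x[[tb]]
    if (!is.data.frame(t)) {
      v <- rbind(v, violation(tb, "table_type", sprintf("%s is not a data.frame", tb)))
    } else if (!identical(rownames(t), expected)) {
      v <- rbind(v, violation(
        tb, "table_rows",
        sprintf("%s row names disagree with %s names in count or order", tb, if (tb == "obs") "cell" else "gene")
      ))
    }
  }

  for (r in names(x$reductions)) {
    e <- x$reductions[[r]]
    if (nrow(e) != n_cells) {
      v <- rbind(v, violation(
        sprintf("reduction %s", r), "embedding_rows",
        sprintf("embedding has %d rows for %d cells", nrow(e), n_cells)
      ))
    }
    if (ncol(e) < 1) {
      v <- rbind(v, violation(
        sprintf("reduction %s", r), "embedding_dims",
        "embedding must have at least one dimension"
      ))
    }
    if (anyNA(e) || any(!is.finite(e))) {
      v <- rbind(v, violation(
        sprintf("reduction %s", r), "embedding_finite",
        "embedding contains non-finite values"
      ))
    }
  }

  for (g in names(x$graphs)) {
    w <- x$graphs[[g]]
    if (nrow(w) != ncol(w) || nrow(w) != n_cells) {
      v <- rbind(v, violation(
        sprintf("graph %s", g), "graph_square",
        sprintf("graph is %d x %d for %d cells", nrow(w), ncol(w), n_cells)
      ))
    }
    vals <- if (inherits(w, "sparseMatrix")) w@x else as.numeric(w)
    if (any(!is.finite(vals))) {
      v <- rbind(v, violation(
        sprintf("graph %s", g), "graph_finite",
        "graph contains non-finite weights"
      ))
    } else if (any(vals < 0)) {
      v <- rbind(v, violation(
        sprintf("graph %s", g), "graph_nonnegative",
        "graph contains negative weights"
      ))
    }
  }

  if (!is.null(x$spatial)) {
    for (s in names(x$spatial)) {
      v <- rbind(v, validate_spatial_block(x$spatial[[s]], n_cells, sprintf("spatial %s", s)))
    }
  }
  v
}

#' Describe every difference between two containers
#'
#' Exact comparison of all components: names, layer values (bit-for-bit,
#' including sparse structure), tables with factor levels, embeddings,
#' graphs and spatial blocks.  Useful to verify round trips.
#'
#' @param a,b two [sc_container()]s.
#' @return character vector of difference descriptions; `character(0)` means
#'   the containers are equal in every component.
#' @export
container_diff <- function(a, b) {
  d <- character()
  note <- function(fmt, ...) d <<- c(d, sprintf(fmt, ...))

  if (!identical(a$cell_names, b$cell_names)) note("cell_names differ")
  if (!identical(a$gene_names, b$gene_names)) note("gene_names differ")

  mat_equal <- function(x, y) {
    if (inherits(x, "sparseMatrix") != inherits(y, "sparseMatrix")) {
      return(FALSE)
    }
    if (inherits(x, "sparseMatrix")) {
      identical(x@i, y@i) && identical(x@p, y@p) && identical(x@x, y@x) &&
        identical(x@Dim, y@Dim) && identical(dimnames(x), dimnames(y))
    } else {
      identical(unname(x), unname(y)) && identical(dimnames(x), dimnames(y))
    }
  }

  if (!identical(names(a$assays), names(b$assays))) {
    note("assay names differ: %s vs %s", toString(names(a$assays)), toString(names(b$assays)))
  } else {
    for (an in names(a$assays)) {
      if (!identical(names(a$assays[[an]]), names(b$assays[[an]]))) {
        note("assay %s layer names differ", an)
        next
      }
      for (ln in names(a$assays[[an]])) {
        if (!mat_equal(a$assays[[an]][[ln]], b$assays[[an]][[ln]])) {
          note("assay %s layer %s values differ", an, ln)
        }
      }
    }
  }

  for (tb in c("obs", "var")) {
    if (!identical(a[[tb]], b[[tb]])) note("%s tables differ", tb)
  }

  if (!identical(names(a$reductions), names(b$reductions))) {
    note("reduction names differ")
  } else {
    for (rn in names(a$reductions)) {
      if (!mat_equal(a$reductions[[rn]], b$reductions[[rn]])) {
        note("reduction %s differs", rn)
      }
    }
  }

  if (!identical(names(a$graphs), names(b$graphs))) {
    note("graph names differ")
  } else {
    for (gn in names(a$graphs)) {
      if (!mat_equal(a$graphs[[gn]], b$graphs[[gn]])) note("graph %s differs", gn)
    }
  }

  sp_a <- a$spatial
  sp_b <- b$spatial
  if (is.null(sp_a) != is.null(sp_b)) {
    note("spatial presence differs")
  } else if (!is.null(sp_a)) {
    if (!identical(names(sp_a), names(sp_b))) {
      note("spatial sample names differ")
    } else {
      for (sn in names(sp_a)) {
        if (!identical(unclass(sp_a[[sn]]), unclass(sp_b[[sn]]))) {
          note("spatial sample %s differs", sn)
        }
      }
    }
  }
  d
}
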