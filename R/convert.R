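#' Save a single-cell object to the unified .h5 format
#'
#' Accepts either an [sc_container()] (written directly) or a Seurat object
#' (adapted first with [as_sc_container()]).  Re-saving a loaded object
#' yields a file that reads back equal.
#'
#' @param obj an `sc_container` or a `Seurat` object.
#' @param path output path.
#' @param block_size,compression passed to [write_h5()].
#' @return `path`, invisibly.
#' @seealso [load_h5()]
#' @export
save_h5 <- function(obj, path, block_size = 5000, compression = 4) {
  if (inherits(obj, "sc_container")) {
    return(write_h5(obj, path, block_size = block_size, compression = compression))
  }
  if (inherits(obj, "Seurat")) {
    return(write_h5(as_sc_container(obj), path,
      block_size = block_size,
      compression = compression
    ))
  }
  stop_parameter(sprintf(
    "save_h5: cannot convert an object of class '%s'; supported: sc_container, Seurat",
    class(obj)[1]
  ))
}

#' Load a .h5 file as a container or as a host-native object
#'
#' `read_type` selects the returned representation: `"seurat"` (the default,
#' requiring the Seurat packages) maps layers, annotations, reductions,
#' graphs and spatial blocks onto a `Seurat` object via [to_seurat()];
#' `"container"` returns the ecosystem-free [sc_container()] and is always
#' available.
#'
#' @param path path to a conforming file.
#' @param read_type `"seurat"` or `"container"`.
#' @return the requested object.
#' @export
load_h5 <- function(path, read_type = c("seurat", "container")) {
  read_type <- tryCatch(match.arg(read_type),
    error = function(e) {
      stop_parameter(sprintf(
        "load_h5: unknown read_type '%s'; use \"seurat\" or \"container\"",
        paste(read_type, collapse = ", ")
      ))
    }
  )
  x <- read_h5(path)
  switch(read_type,
    container = x,
    seurat = to_seurat(x)
  )
}

require_seurat <- function() {
  if (!requireNamespace("SeuratObject", quietly = TRUE) ||
    !requireNamespace("Seurat", quietly = TRUE)) {
    stop_parameter("the Seurat adapter requires the 'Seurat' and 'SeuratObject' packages")
  }
}

#' Convert a container to a Seurat object
#'
#' Layers are transposed to Seurat's genes x cells orientation (sparse
#' layers become `dgCMatrix`), `obs` becomes `meta.data`, `var` the assay's
#' feature-level `meta.data`, reductions become `DimReduc` objects (the key
#' is taken from the stored dimension labels when they follow the
#' `prefix_number` convention), and graphs become `Graph` objects.  Spatial
#' blocks are carried in `@misc$sch5_spatial` — Seurat's Visium image
#' classes have no public constructor from raw parts — and a notice is
#' emitted.  [as_sc_container()] inverts the mapping;
#' `as_sc_container(to_seurat(x))` equals `x` component for component.
#'
#' @param x an [sc_container()] with at least one assay layer.
#' @return a `Seurat` object.
#' @export
to_seurat <- function(x) {
  require_seurat()
  if (length(x$assays) == 0 || length(x$assays[[1]]) == 0) {
    stop_parameter("to_seurat: container has no assay layers")
  }
  v <- validate_container(x)
  if (nrow(v) > 0) {
    stop_validation("to_seurat: container is invalid; see validate_container()")
  }

  make_assay <- function(layers) {
    first <- names(layers)[1]
    a <- SeuratObject::CreateAssay5Object(counts = Matrix::t(layers[[first]]))
    if (first != "counts") {
      SeuratObject::LayerData(a, first) <- Matrix::t(layers[[first]])
      SeuratObject::LayerData(a, "counts") <- NULL
    }
    for (ln in setdiff(names(layers), first)) {
      SeuratObject::LayerData(a, ln) <- Matrix::t(layers[[ln]])
    }
    if (ncol(x$var) > 0) {
      methods::slot(a, "meta.data") <- x$var
    }
    a
  }

  assay_names <- names(x$assays)
  obj <- SeuratObject::CreateSeuratObject(
    counts = make_assay(x$assays[[1]]),
    assay = assay_names[1]
  )
  for (an in assay_names[-1]) {
    obj[[an]] <- make_assay(x$assays[[an]])
  }
  methods::slot(obj, "meta.data") <- x$obs

  for (rn in names(x$reductions)) {
    emb <- x$reductions[[rn]]
    labels <- colnames(emb)
    key <- NULL
    if (!is.null(labels)) {
      pref <- unique(sub("_[0-9]+$", "_", labels))
      if (length(pref) == 1 && grepl("^[A-Za-z][A-Za-z0-9.]*_$", pref) &&
        all(grepl("_[0-9]+$", labels))) {
        key <- pref
      }
    }
    if (is.null(key)) {
      key <- paste0(gsub("[^A-Za-z0-9]", "", rn), "_")
      colnames(emb) <- paste0(key, seq_len(ncol(emb)))
    }
    obj[[rn]] <- SeuratObject::CreateDimReducObject(
      embeddings = emb, key = key, assay = assay_names[1]
    )
  }

  for (gn in names(x$graphs)) {
    g <- SeuratObject::as.Graph(x$graphs[[gn]])
    methods::slot(g, "assay.used") <- assay_names[1]
    obj@graphs[[gn]] <- g
  }

  if (!is.null(x$spatial)) {
    obj@misc$sch5_spatial <- x$spatial
    message(
      "to_seurat: spatial samples stored in @misc$sch5_spatial (",
      paste(names(x$spatial), collapse = ", "),
      "); Seurat's Visium image classes cannot be built from raw parts"
    )
  }
  obj
}

#' Convert a Seurat object to a container
#'
#' The inverse of [to_seurat()].  Assay layers are transposed back to
#' cells x genes; `meta.data` becomes `obs`; the default assay's feature
#' metadata becomes `var`; embeddings and graphs map directly.  Host
#' components outside the container model (`commands`, `tools`, the active
#' identity, non-adapter `misc` entries, and any assay whose feature set
#' differs from the default assay's) are dropped with a notice — the names
#' are returned in the `"dropped"` attribute, never silently discarded.
#'
#' @param obj a `Seurat` object.
#' @return an [sc_container()].
#' @export
as_sc_container <- function(obj) {
  require_seurat()
  if (!inherits(obj, "Seurat")) {
    stop_parameter(sprintf("as_sc_container: expected a Seurat object, got '%s'", class(obj)[1]))
  }
  dropped <- character()
  cells <- SeuratObject::Cells(obj)
  default_assay <- SeuratObject::DefaultAssay(obj)
  genes <- rownames(obj[[default_assay]])

  assays <- list()
  for (an in SeuratObject::Assays(obj)) {
    a <- obj[[an]]
    if (!identical(rownames(a), genes)) {
      dropped <- c(dropped, sprintf("assay %s (feature set differs from '%s')", an, default_assay))
      next
    }
    layers <- list()
    for (ln in SeuratObject::Layers(a)) {
      layers[[ln]] <- Matrix::t(SeuratObject::LayerData(a, ln))
    }
    assays[[an]] <- layers
  }
  # default assay first, matching the container convention
  assays <- assays[c(default_assay, setdiff(names(assays), default_assay))]

  var <- methods::slot(obj[[default_assay]], "meta.data")
  if (ncol(var) == 0) var <- data.frame(row.names = genes)

  reductions <- lapply(
    stats::setNames(nm = SeuratObject::Reductions(obj)),
    function(rn) SeuratObject::Embeddings(obj, rn)
  )
  graphs <- lapply(
    stats::setNames(nm = SeuratObject::Graphs(obj)),
    function(gn) as(obj@graphs[[gn]], "CsparseMatrix")
  )

  spatial <- NULL
  misc <- obj@misc
  if (!is.null(misc$sch5_spatial)) {
    spatial <- misc$sch5_spatial
    misc$sch5_spatial <- NULL
  }
  if (length(misc) > 0) {
    dropped <- c(dropped, paste0("misc$", names(misc)))
  }
  if (length(obj@images) > 0) {
    dropped <- c(dropped, paste0("image ", names(obj@images), " (host-native image class)"))
  }
  if (length(methods::slot(obj, "commands")) > 0) dropped <- c(dropped, "commands")
  if (length(methods::slot(obj, "tools")) > 0) dropped <- c(dropped, "tools")

  if (length(dropped) > 0) {
    message(
      "as_sc_container: dropping host components outside the container model: ",
      paste(dropped, collapse = "; ")
    )
  }
  out <- sc_container(
    assays = assays, obs = obj@meta.data, var = var,
    reductions = reductions, graphs = graphs, spatial = spatial,
    cell_names = cells, gene_names = genes
  )
  attr(out, "dropped") <- dropped
  out
}
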