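#' Deterministic synthetic single-cell containers
#'
#' Generates containers that emulate the structure of real scRNA-seq and
#' Visium-style objects at desk scale — sparse nonnegative integer counts
#' with cell-type-specific gene programs, factor/numeric/string annotation
#' columns, PCA/UMAP-like embeddings, exact k-nearest-neighbor (`nn`) and
#' shared-nearest-neighbor (`snn`) graphs, and an optional spatial sample —
#' so every codec path is testable without downloading data.  The same seed
#' always yields the identical container; the caller's RNG state is left
#' untouched.
#'
#' Counts are drawn by giving each cell a number of expressed genes around
#' the requested density, choosing the genes with cell-type-weighted
#' probabilities (each type overexpresses its own gene program), and drawing
#' values from a negative binomial (size 2, mean 5, shifted to be >= 1) —
#' mimicking scRNA-seq sparsity without any modeling claim.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param density target fraction of nonzero entries in `(0, 1]`.
#' @param n_cell_types number of cell-type factor levels in `obs`.
#' @param reductions named list mapping reduction name to dimension count.
#' @param graphs character vector of graph names to build (subset of
#'   `c("nn", "snn")`).
#' @param k_neighbors neighbors per cell for the graphs.
#' @param with_spatial also attach a 64 x 64 x 3 spatial sample with one
#'   spot per cell and the four standard Visium scale factors.
#' @param seed integer seed; same seed, same container.
#' @return a valid [sc_container()].
#' @examples
#' x <- make_container(n_cells = 50, n_genes = 20, seed = 1)
#' nrow(validate_container(x)) # 0
#' @export
make_container <- function(n_cells = 1000, n_genes = 500, density = 0.05,
                           n_cell_types = 3,
                           reductions = list(pca = 50L, umap = 2L),
                           graphs = c("nn", "snn"), k_neighbors = 10,
                           with_spatial = FALSE, seed = 42) {
  if (n_cells < 1 || n_genes < 1) {
    stop_parameter("make_container: n_cells and n_genes must be positive")
  }
  if (density <= 0 || density > 1) {
    stop_parameter("make_container: density must be in (0, 1]")
  }
  if (length(graphs) > 0 && k_neighbors >= n_cells) {
    stop_parameter("make_container: k_neighbors must be smaller than n_cells")
  }
  with_seed(seed, {
    cell_names <- sprintf("cell-%04d", seq_len(n_cells))
    gene_names <- sprintf("gene-%04d", seq_len(n_genes))
    type_levels <- paste0("type_", seq_len(n_cell_types))
    cell_type <- factor(
      sample(type_levels, n_cells, replace = TRUE),
      levels = type_levels
    )

    # per-type gene weights: each type overexpresses a dedicated gene slice
    w <- matrix(1, n_cell_types, n_genes)
    slice <- ceiling(n_genes / n_cell_types)
    for (t in seq_len(n_cell_types)) {
      lo <- (t - 1) * slice + 1
      w[t, lo:min(t * slice, n_genes)] <- 3
    }

    n_expr <- pmax(1L, stats::rbinom(n_cells, n_genes, density))
    js <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      js[[i]] <- sample.int(n_genes, n_expr[i], prob = w[as.integer(cell_type[i]), ])
    }
    ii <- rep.int(seq_len(n_cells), n_expr)
    jj <- unlist(js, use.names = FALSE)
    vals <- stats::rnbinom(length(jj), size = 2, mu = 5) + 1
    counts <- Matrix::sparseMatrix(
      i = ii, j = jj, x = as.double(vals),
      dims = c(n_cells, n_genes),
      dimnames = list(cell_names, gene_names)
    )

    obs <- data.frame(
      cell_type = cell_type,
      total_counts = Matrix::rowSums(counts),
      sample_id = rep("sample-1", n_cells),
      row.names = cell_names, check.names = FALSE
    )
    var <- data.frame(
      gene_symbol = toupper(gsub("-", "", gene_names)),
      mean_counts = Matrix::colMeans(counts),
      row.names = gene_names, check.names = FALSE
    )

    red <- list()
    for (rn in names(reductions)) {
      d <- as.integer(reductions[[rn]])
      e <- matrix(stats::rnorm(n_cells * d), n_cells, d)
      # separate the cell types so neighbor graphs are structured
      e[, 1] <- e[, 1] + 5 * as.integer(cell_type)
      prefix <- switch(rn, pca = "PC_", umap = "UMAP_", paste0(toupper(rn), "_"))
      dimnames(e) <- list(cell_names, paste0(prefix, seq_len(d)))
      red[[rn]] <- e
    }

    gr <- list()
    if (length(graphs) > 0) {
      base <- if (length(red) > 0) red[[1]] else matrix(stats::rnorm(n_cells * 2), n_cells, 2)
      nn <- knn_graph(base, k_neighbors)
      dimnames(nn) <- list(cell_names, cell_names)
      for (gn in graphs) {
        gr[[gn]] <- switch(gn,
          nn = nn,
          snn = snn_graph(nn, k_neighbors),
          stop_parameter(sprintf("make_container: unknown graph '%s'", gn))
        )
      }
    }

    spatial <- NULL
    if (with_spatial) {
      img <- array(sample.int(256, 64 * 64 * 3, replace = TRUE) - 1L, dim = c(64, 64, 3))
      coords <- cbind(stats::runif(n_cells, 1, 63), stats::runif(n_cells, 1, 63))
      spatial <- list(sample1 = spatial_block(
        img, coords,
        scale_factors = list(
          spot_diameter_fullres = 10, fiducial_diameter_fullres = 16,
          tissue_hires_scalef = 0.5, tissue_lowres_scalef = 0.1
        ),
        resolution = "fullres"
      ))
    }

    sc_container(
      counts = counts, obs = obs, var = var,
      reductions = red, graphs = gr, spatial = spatial,
      cell_names = cell_names, gene_names = gene_names
    )
  })
}

# Exact k-nearest-neighbor graph (Euclidean, ties broken by index order).
# Edge weight 1 for each directed neighbor relation; no self-edges.
knn_graph <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  jj <- integer(n * k)
  for (i in seq_len(n)) {
    jj[((i - 1) * k + 1):(i * k)] <- order(d[i, ])[seq_len(k)]
  }
  Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = jj, x = 1,
    dims = c(n, n)
  )
}

# Shared-nearest-neighbor graph: Jaccard overlap of neighbor sets,
# s / (2k - s) for s shared neighbors, zeros dropped.
snn_graph <- function(nn, k) {
  shared <- Matrix::tcrossprod(nn)
  x <- shared@x / (2 * k - shared@x)
  out <- shared
  out@x <- x
  Matrix::drop0(out)
}

.CORRUPTIONS <- c(
  "drop_names_obs", "shuffle_indptr", "out_of_range_code",
  "nonsquare_graph", "wrong_channels", "coords_count_mismatch"
)

#' Produce a deliberately corrupted copy of a .h5 file
#'
#' Applies one named mutation to a copy of a conforming file, chosen so
#' that [validate_h5()] reports exactly the targeted violation and
#' [read_h5()] refuses the file.  Used to exercise every error path of the
#' validator.
#'
#' Mutations: `drop_names_obs` (removes the cell-name dataset),
#' `shuffle_indptr` (makes a block's row offsets non-monotone),
#' `out_of_range_code` (writes a factor code equal to the category count),
#' `nonsquare_graph` (declares a graph shape of `(n, n - 1)`),
#' `wrong_channels` (rewrites the spatial image with 2 channels),
#' `coords_count_mismatch` (drops one spot coordinate row).  The last two
#' require the base file to contain a spatial sample; the graph mutation
#' requires a graph; the factor mutation a factor column in `obs`.
#'
#' @param base path to a conforming file (left untouched).
#' @param mutation one of the six documented mutation names.
#' @param out path for the corrupted copy.
#' @return `out`, invisibly.
#' @export
make_corrupted_file <- function(base, mutation, out = tempfile(fileext = ".h5")) {
  if (length(mutation) != 1 || !(mutation %in% .CORRUPTIONS)) {
    stop_parameter(sprintf(
      "make_corrupted_file: unknown mutation '%s'; expected one of: %s",
      paste(mutation, collapse = ", "), paste(.CORRUPTIONS, collapse = ", ")
    ))
  }
  if (!file.copy(base, out, overwrite = TRUE)) {
    stop_io(sprintf("make_corrupted_file: cannot copy '%s' to '%s'", base, out))
  }
  ls_df <- rhdf5::h5ls(out)
  find_one <- function(pattern, what) {
    hits <- paste0(ls_df$group, "/", ls_df$name)
    hits <- hits[grepl(pattern, hits)]
    if (length(hits) == 0) {
      stop_parameter(sprintf("make_corrupted_file: base file has no %s", what))
    }
    sub("^/", "", hits[1])
  }

  switch(mutation,
    drop_names_obs = {
      rhdf5::h5delete(out, "names_obs")
    },
    shuffle_indptr = {
      nm <- find_one("^/assay/.*/block_[0-9]+/indptr$", "blocked CSR layer")
      p <- as.double(rhdf5::h5read(out, nm, bit64conversion = "double"))
      if (length(unique(p)) < 2) {
        stop_parameter("make_corrupted_file: block indptr is constant; cannot break monotonicity")
      }
      h5_replace_vec(out, nm, rev(p), h5type = "H5T_STD_I32LE")
    },
    out_of_range_code = {
      nm <- find_one("^/obs/.*/codes$", "factor column in obs")
      codes <- as.integer(rhdf5::h5read(out, nm))
      cats <- rhdf5::h5read(out, sub("/codes$", "/categories", nm))
      codes[1] <- length(cats)
      h5_replace_vec(out, nm, codes, h5type = "H5T_STD_I32LE")
    },
    nonsquare_graph = {
      gname <- find_one("^/graphs/[^/]+$", "graph")
      shape <- as.double(h5_attrs(out, gname)$shape)
      rhdf5::h5deleteAttribute(out, gname, "shape")
      h5_put_attr(out, gname, "shape", c(shape[1], shape[1] - 1))
    },
    wrong_channels = {
      nm <- find_one("^/images/[^/]+/image$", "spatial image")
      img <- rhdf5::h5read(out, nm)
      storage.mode(img) <- "integer"
      rhdf5::h5delete(out, nm)
      h5_write_array(out, nm, img[, , 1:2, drop = FALSE], h5type = "H5T_STD_U8LE")
    },
    coords_count_mismatch = {
      nm <- find_one("^/images/[^/]+/coords$", "spot coordinates")
      xy <- rhdf5::h5read(out, nm)
      rhdf5::h5delete(out, nm)
      h5_write_array(out, nm, xy[-1, , drop = FALSE])
    }
  )
  invisible(out)
}
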