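#' Spatial sample block (Visium-style)
#'
#' One spatial sample bundles a tissue image (`H x W x 3`, 8-bit color), the
#' full-resolution pixel position of each spot (`n_spots x 2`, ordered as
#' (pixel row, pixel col) and aligned to the container's cell order), and a
#' set of named positive scale factors relating image resolutions.  The four
#' standard Visium keys (`spot_diameter_fullres`, `fiducial_diameter_fullres`,
#' `tissue_hires_scalef`, `tissue_lowres_scalef`) are required; extra keys
#' are preserved verbatim.
#'
#' Spot coordinates are expected to fall inside the image after rounding;
#' positions outside produce a warning, not an error, since fiducial margins
#' routinely place spots beyond the cropped tissue image.
#'
#' @param image integer array `H x W x 3` with values in 0..255.
#' @param coords numeric matrix `n_spots x 2`, full-resolution pixel
#'   positions (row, col).
#' @param scale_factors named list/vector of positive finite scale factors.
#' @param resolution which image this is (`"fullres"`, `"hires"` or
#'   `"lowres"`); recorded as an attribute on disk.
#' @return an object of class `"spatial_block"`.
#' @export
spatial_block <- function(image, coords, scale_factors,
                          resolution = c("fullres", "hires", "lowres")) {
  resolution <- match.arg(resolution)
  image <- as.array(image)
  storage.mode(image) <- "integer"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- NULL
  s <- structure(
    list(
      image = image, coords = coords,
      scale_factors = as.list(scale_factors), resolution = resolution
    ),
    class = "spatial_block"
  )
  v <- validate_spatial_block(s, n_cells = NULL, "spatial_block")
  hard <- v[v$rule != "coords_outside_image", , drop = FALSE]
  if (nrow(hard) > 0) {
    stop_schema(paste0("spatial_block: ", hard$message[1]))
  }
  if (any(v$rule == "coords_outside_image")) {
    warning(v$message[v$rule == "coords_outside_image"][1], call. = FALSE)
  }
  s
}

#' @export
print.spatial_block <- function(x, ...) {
  cat(sprintf(
    "<spatial_block> image %d x %d x %d (%s), %d spots, %d scale factors\n",
    dim(x$image)[1], dim(x$image)[2], dim(x$image)[3], x$resolution,
    nrow(x$coords), length(x$scale_factors)
  ))
  invisible(x)
}

.REQUIRED_SCALE_FACTORS <- c(
  "spot_diameter_fullres", "fiducial_diameter_fullres",
  "tissue_hires_scalef", "tissue_lowres_scalef"
)

# Shared between validate_container and the constructor.  `n_cells = NULL`
# skips the spot-count check.
validate_spatial_block <- function(s, n_cells, component) {
  v <- no_violations()
  d <- dim(s$image)
  if (length(d) != 3 || d[3] != 3) {
    v <- rbind(v, violation(
      component, "image_channels",
      sprintf(
        "image must have 3 channels, got dims (%s)",
        paste(d, collapse = ", ")
      )
    ))
  }
  if (length(dim(s$coords)) != 2 || ncol(s$coords) != 2) {
    v <- rbind(v, violation(component, "coords_shape", "coords must be n_spots x 2"))
    return(v)
  }
  if (!is.null(n_cells) && nrow(s$coords) != n_cells) {
    v <- rbind(v, violation(
      component, "coords_count_mismatch",
      sprintf("%d spot coordinates for %d cells", nrow(s$coords), n_cells)
    ))
  }
  sf <- unlist(s$scale_factors)
  missing_sf <- setdiff(.REQUIRED_SCALE_FACTORS, names(s$scale_factors))
  if (length(missing_sf) > 0) {
    v <- rbind(v, violation(
      component, "scale_factor_missing",
      sprintf("missing scale factor(s): %s", paste(missing_sf, collapse = ", "))
    ))
  }
  if (length(sf) > 0 && (any(!is.finite(sf)) || any(sf <= 0))) {
    v <- rbind(v, violation(
      component, "scale_factor_positive",
      "scale factors must be finite and > 0"
    ))
  }
  if (length(d) == 3 && nrow(s$coords) > 0) {
    r <- round(s$coords)
    if (any(r[, 1] < 0 | r[, 1] >= d[1] | r[, 2] < 0 | r[, 2] >= d[2])) {
      v <- rbind(v, violation(
        component, "coords_outside_image",
        sprintf(
          "some spot coordinates fall outside the %d x %d image after rounding",
          d[1], d[2]
        )
      ))
    }
  }
  v
}

#' Spot coordinates at a stored image resolution
#'
#' Multiplies the full-resolution spot positions elementwise by the named
#' tissue scale factor (`tissue_hires_scalef` or `tissue_lowres_scalef`);
#' `"fullres"` applies a factor of 1 and returns the coordinates unchanged.
#'
#' @param s a [spatial_block()].
#' @param which `"fullres"`, `"hires"` or `"lowres"`.
#' @return an `n_spots x 2` numeric matrix.
#' @export
scaled_coords <- function(s, which = c("fullres", "hires", "lowres")) {
  which <- match.arg(which)
  if (which == "fullres") {
    return(s$coords)
  }
  key <- paste0("tissue_", which, "_scalef")
  if (is.null(s$scale_factors[[key]])) {
    stop_parameter(sprintf("scaled_coords: scale factor '%s' not present", key))
  }
  s$coords * s$scale_factors[[key]]
}

# On-disk layout: images/<sample>/{image, coords, scale_factors/<name>} ----

write_spatial <- function(fid, sample_name, s, level = 4L) {
  base <- paste0("images/", sample_name)
  rhdf5::h5createGroup(fid, base)
  h5_write_array(fid, paste0(base, "/image"), s$image,
    level = level,
    h5type = "H5T_STD_U8LE"
  )
  h5_put_attr(fid, paste0(base, "/image"), "resolution", s$resolution)
  h5_write_array(fid, paste0(base, "/coords"), s$coords, level = level)
  h5_put_attr(fid, paste0(base, "/coords"), "axes", "pixel_row,pixel_col")
  rhdf5::h5createGroup(fid, paste0(base, "/scale_factors"))
  for (nm in names(s$scale_factors)) {
    rhdf5::h5write(as.double(s$scale_factors[[nm]]), fid, paste0(base, "/scale_factors/", nm))
  }
  h5_put_attr(fid, base, "element_order", names(s$scale_factors))
  invisible(NULL)
}

read_spatial <- function(fid, sample_name) {
  base <- paste0("images/", sample_name)
  for (part in c("", "/image", "/coords", "/scale_factors")) {
    if (!rhdf5::H5Lexists(fid, paste0(base, part))) {
      stop_schema(sprintf("read_spatial: missing /%s%s", base, part))
    }
  }
  img <- h5_read(fid, paste0(base, "/image"))
  storage.mode(img) <- "integer"
  resolution <- h5_attrs(fid, paste0(base, "/image"))$resolution
  if (is.null(resolution)) resolution <- "fullres"
  coords <- h5_read(fid, paste0(base, "/coords"))
  order <- h5_attrs(fid, base)$element_order
  ls_df <- rhdf5::h5ls(fid)
  sf_names <- h5_children(ls_df, paste0("/", base, "/scale_factors"))
  if (!is.null(order)) sf_names <- intersect(as.character(order), sf_names)
  sf <- lapply(sf_names, function(nm) {
    as.double(h5_read(fid, paste0(base, "/scale_factors/", nm)))
  })
  names(sf) <- sf_names
  suppressWarnings(spatial_block(img, coords, sf, resolution = resolution))
}
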