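# Internal rhdf5 helpers.
#
# All writers accept either a file path or an open H5IdComponent (file
# handle).  Bulk writes open the file once and pass the handle down; path
# accepting variants exist for one-off surgical edits (corrupted-fixture
# generation).

h5_is_handle <- function(loc) inherits(loc, "H5IdComponent")

# Open `path` (or pass a handle through), run fn(fid), always close what we
# opened.
with_h5 <- function(loc, fn, create = FALSE) {
  if (h5_is_handle(loc)) {
    return(fn(loc))
  }
  fid <- if (create) rhdf5::H5Fcreate(loc) else rhdf5::H5Fopen(loc)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  fn(fid)
}

h5_exists <- function(loc, name) {
  with_h5(loc, function(fid) rhdf5::H5Lexists(fid, name))
}

# Write a 1-D dataset with gzip compression.  `h5type` may name an explicit
# HDF5 type ("H5T_STD_I64LE", "H5T_STD_I32LE", "H5T_STD_I8LE", ...); strings
# are written variable-length UTF-8.  Zero-length datasets are created
# contiguous (chunked storage cannot have a zero-size chunk).
h5_write_vec <- function(loc, name, x, level = 4L, h5type = NULL) {
  n <- length(x)
  chunk <- if (n > 0) min(n, 262144L) else NULL
  lvl <- if (n > 0) level else 0L
  if (is.character(x)) {
    rhdf5::h5createDataset(loc, name,
      dims = n, storage.mode = "character",
      size = NULL, encoding = "UTF-8", chunk = chunk, level = lvl
    )
  } else if (!is.null(h5type)) {
    rhdf5::h5createDataset(loc, name,
      dims = n, H5type = h5type,
      chunk = chunk, level = lvl
    )
  } else {
    rhdf5::h5createDataset(loc, name,
      dims = n, storage.mode = storage.mode(x),
      chunk = chunk, level = lvl
    )
  }
  if (n > 0) {
    rhdf5::h5write(x, loc, name)
  }
  invisible(NULL)
}

# Write an n-D numeric dataset (matrices, image arrays).
h5_write_array <- function(loc, name, x, level = 4L, h5type = NULL) {
  d <- dim(x)
  if (any(d == 0)) {
    if (is.null(h5type)) {
      rhdf5::h5createDataset(loc, name, dims = d, storage.mode = storage.mode(x))
    } else {
      rhdf5::h5createDataset(loc, name, dims = d, H5type = h5type)
    }
    return(invisible(NULL))
  }
  if (is.null(h5type)) {
    rhdf5::h5createDataset(loc, name,
      dims = d, storage.mode = storage.mode(x),
      chunk = d, level = level
    )
  } else {
    rhdf5::h5createDataset(loc, name,
      dims = d, H5type = h5type,
      chunk = d, level = level
    )
  }
  rhdf5::h5write(x, loc, name)
  invisible(NULL)
}

# Attach an attribute to an existing object (group or dataset).
h5_put_attr <- function(loc, objname, name, value) {
  with_h5(loc, function(fid) {
    oid <- rhdf5::H5Oopen(fid, objname)
    on.exit(rhdf5::H5Oclose(oid), add = TRUE)
    if (is.character(value)) {
      rhdf5::h5writeAttribute(value, oid, name,
        variableLengthString = TRUE, encoding = "UTF-8",
        asScalar = length(value) == 1
      )
    } else {
      rhdf5::h5writeAttribute(value, oid, name, asScalar = length(value) == 1)
    }
  })
}

# Read all attributes of an object, dropping rhdf5 bookkeeping attributes.
h5_attrs <- function(loc, objname) {
  a <- if (h5_is_handle(loc)) {
    rhdf5::h5readAttributes(loc, objname)
  } else {
    rhdf5::h5readAttributes(loc, objname)
  }
  a[!grepl("^rhdf5-", names(a))]
}

h5_read <- function(loc, name) {
  rhdf5::h5read(loc, name, bit64conversion = "double")
}

# Children (immediate members) of a group, in stored (alphabetical) order.
h5_children <- function(ls_df, group) {
  ls_df$name[ls_df$group == group]
}

# Size in bytes of a dataset's stored integer/float type (4 or 8).
h5_type_size <- function(loc, name) {
  with_h5(loc, function(fid) {
    did <- rhdf5::H5Dopen(fid, name)
    on.exit(rhdf5::H5Dclose(did), add = TRUE)
    tid <- rhdf5::H5Dget_type(did)
    rhdf5::H5Tget_size(tid)
  })
}

# Replace a 1-D dataset in an existing file, preserving nothing (used by
# make_corrupted_file).
h5_replace_vec <- function(path, name, x, h5type = NULL) {
  rhdf5::h5delete(path, name)
  h5_write_vec(path, name, x, h5type = h5type)
}
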