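make_block <- function(n_spots = 100, h = 64, w = 64) {
  set.seed(31)
  spatial_block(
    array(sample.int(256, h * w * 3, replace = TRUE) - 1L, dim = c(h, w, 3)),
    cbind(runif(n_spots, 0, h - 1), runif(n_spots, 0, w - 1)),
    scale_factors = list(
      spot_diameter_fullres = 10, fiducial_diameter_fullres = 16,
      tissue_hires_scalef = 0.5, tissue_lowres_scalef = 0.1
    )
  )
}

test_that("spatial blocks round-trip byte-exactly through the images group", {
  s <- make_block()
  x <- make_container(n_cells = 100, n_genes = 20, seed = 41)
  x$spatial <- list(sampleA = s)
  f <- local_h5(x)
  y <- read_h5(f)
  expect_identical(y$spatial$sampleA$image, s$image)
  expect_identical(y$spatial$sampleA$coords, s$coords)
  expect_identical(y$spatial$sampleA$scale_factors, s$scale_factors)
  expect_identical(y$spatial$sampleA$resolution, s$resolution)
})

test_that("extra scale factors are preserved verbatim", {
  s <- make_block()
  s$scale_factors$regist_target_img_scalef <- 0.25
  x <- make_container(n_cells = 100, n_genes = 20, seed = 41)
  x$spatial <- list(s1 = s)
  y <- read_h5(local_h5(x))
  expect_equal(y$spatial$s1$scale_factors$regist_target_img_scalef, 0.25)
})

test_that("malformed spatial blocks are refused with named schema errors", {
  img2 <- array(0L, dim = c(8, 8, 2))
  expect_error(
    spatial_block(img2, cbind(1, 1), list(
      spot_diameter_fullres = 10, fiducial_diameter_fullres = 16,
      tissue_hires_scalef = 0.5, tissue_lowres_scalef = 0.1
    )),
    "3 channels",
    class = "sch5_schema_error"
  )
  expect_error(
    spatial_block(array(0L, dim = c(8, 8, 3)), cbind(1, 1), list(
      spot_diameter_fullres = 10, fiducial_diameter_fullres = 16,
      tissue_hires_scalef = 0.5
    )),
    "tissue_lowres_scalef",
    class = "sch5_schema_error"
  )
  expect_error(
    spatial_block(array(0L, dim = c(8, 8, 3)), cbind(1, 1), list(
      spot_diameter_fullres = -1, fiducial_diameter_fullres = 16,
      tissue_hires_scalef = 0.5, tissue_lowres_scalef = 0.1
    )),
    class = "sch5_schema_error"
  )
})

test_that("spots outside the image warn (fiducial margins) but do not error", {
  expect_warning(
    spatial_block(array(0L, dim = c(8, 8, 3)), cbind(20, 4), list(
      spot_diameter_fullres = 10, fiducial_diameter_fullres = 16,
      tissue_hires_scalef = 0.5, tissue_lowres_scalef = 0.1
    )),
    "outside"
  )
})

test_that("coordinate count mismatches are caught at container level", {
  x <- make_container(n_cells = 100, n_genes = 20, seed = 41)
  s <- make_block(n_spots = 99)
  x$spatial <- list(s1 = s)
  v <- validate_container(x)
  expect_equal(v$rule, "coords_count_mismatch")
  expect_error(write_h5(x, tempfile(fileext = ".h5")), class = "sch5_validation_error")
})

test_that("scaled_coords multiplies by the named factor and flags missing ones", {
  s <- make_block(n_spots = 1)
  s$coords <- cbind(100, 200)
  expect_equal(scaled_coords(s, "hires"), cbind(50, 100))
  expect_equal(scaled_coords(s, "lowres"), cbind(10, 20))
  expect_identical(scaled_coords(s, "fullres"), s$coords)
  s$scale_factors$tissue_lowres_scalef <- NULL
  expect_error(scaled_coords(s, "lowres"), "tissue_lowres_scalef",
    class = "sch5_parameter_error"
  )
})
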