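# gridded-layer container, ESRI ASCII I/O, bilinear resampling, cell lookup

test_that("ASCII grid parsing recovers values and registration", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 2", "nrows 2", "xllcorner 10", "yllcorner 40",
    "cellsize 0.5", "NODATA_value -9999",
    "1 2", "3 4"
  ), p)
  r <- read_ascii_grid(p)
  expect_equal(r$values[1, ], c(1, 2)) # north row first
  expect_equal(r$values[2, ], c(3, 4))
  expect_equal(c(r$x_ll, r$y_ll, r$cell_size), c(10, 40, 0.5))

  # centre-registered header converts to the corner convention
  p2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 1", "nrows 1", "xllcenter 10", "yllcenter 40",
    "cellsize 0.5", "NODATA_value -9999", "7"
  ), p2)
  r2 <- read_ascii_grid(p2)
  expect_equal(r2$x_ll, 10 - 0.25)
  expect_equal(r2$y_ll, 40 - 0.25)
})

test_that("malformed ASCII grids fail with the offending key or dimensions", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "yllcorner 0", "cellsize 1", "1 2", "3 4"), p)
  expect_error(read_ascii_grid(p), "xllcorner")
  p2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
    "cellsize 1", "NODATA_value -9999", "1 2 3"
  ), p2)
  expect_error(read_ascii_grid(p2), "dimension mismatch")
  p3 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols two", "nrows 2", "xllcorner 0", "yllcorner 0",
    "cellsize 1", "NODATA_value -9999", "1 2", "3 4"
  ), p3)
  expect_error(read_ascii_grid(p3), "ncols")
})

test_that("write/read round-trips rasters bit-identically, nodata included", {
  r <- rand_grid(10, 10, seed = 31, na_frac = 0.2)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- read_ascii_grid(p)
  expect_identical(r2$values, r$values)
  expect_equal(r2$x_ll, r$x_ll)
  expect_equal(r2$cell_size, r$cell_size)
  # nodata cells are emitted as the sentinel token
  line_north <- readLines(p)[7]
  n_na <- sum(is.na(r$values[1, ]))
  expect_equal(
    lengths(regmatches(line_north, gregexpr("-9999", line_north))), n_na
  )
})

test_that("bilinear resampling is exact on constant and affine fields", {
  src <- raster_grid(matrix(5, 8, 8), 0, 0, 1)
  tmpl <- raster_grid(matrix(0, 6, 6), 0.7, 0.9, 0.9)
  out <- resample_bilinear(src, tmpl)
  inner <- out$values[!is.na(out$values)]
  expect_true(length(inner) > 0)
  expect_equal(inner, rep(5, length(inner)))

  # affine field a*x + b*y + c is reproduced exactly at interior centres
  a <- 2.5
  b <- -1.2
  cc <- 0.3
  src_cc <- cell_centers(src)
  affine <- outer(src_cc$lat, src_cc$lon, function(y, x) a * x + b * y + cc)
  src2 <- raster_grid(affine, 0, 0, 1)
  out2 <- resample_bilinear(src2, tmpl)
  tc <- cell_centers(tmpl)
  expected <- outer(tc$lat, tc$lon, function(y, x) a * x + b * y + cc)
  keep <- !is.na(out2$values)
  expect_equal(out2$values[keep], expected[keep], tolerance = 1e-12)
})

test_that("bilinear weights match the explicit 4-term formula", {
  # source centres at 0.5/1.5; query point offset (tx, ty) from the NW centre
  src <- grid_of(list(c(0, 1), c(2, 3)), x_ll = 0, y_ll = 0, cell_size = 1)
  tx <- 0.25
  ty <- 0.4 # fraction east / fraction south
  tmpl <- raster_grid(matrix(0, 1, 1),
    x_ll = 0.5 + tx - 0.05, y_ll = 2 - (0.5 + ty) - 0.05, cell_size = 0.1
  )
  out <- resample_bilinear(src, tmpl)
  manual <- (1 - ty) * ((1 - tx) * 0 + tx * 1) + ty * ((1 - tx) * 2 + tx * 3)
  expect_equal(out$values[1, 1], manual, tolerance = 1e-9)
})

test_that("bilinear yields nodata beyond the centre lattice and near nodata", {
  src <- grid_of(list(c(0, 1), c(NA, 3)))
  # template centre inside the extent but with a nodata stencil member
  tmpl <- raster_grid(matrix(0, 1, 1), 0.95, 0.95, 0.1)
  expect_true(is.na(resample_bilinear(src, tmpl)$values[1, 1]))
  # outside the source entirely -> extent error
  far <- raster_grid(matrix(0, 2, 2), 100, 100, 1)
  expect_error(resample_bilinear(src, far), "disjoint")
})

test_that("cell lookup follows the half-open east/north-exclusive convention", {
  r <- raster_grid(matrix(0, 4, 5), 0, 0, 1)
  expect_equal(unname(cell_index(r, 0, 0)[1, ]), c(4L, 1L)) # lower-left corner
  # interior vertical edge belongs to the right-hand cell
  expect_equal(cell_index(r, 2, 0.5)[1, "col"], c(col = 3L))
  # interior horizontal edge belongs to the northern cell
  expect_equal(cell_index(r, 0.5, 2)[1, "row"], c(row = 2L))
  expect_error(cell_index(r, 5, 0), "outside")
  expect_error(cell_index(r, 0, 4), "outside")
})

test_that("cell lookup agrees with a brute-force box-membership scan", {
  r <- raster_grid(matrix(0, 7, 9), -3, 2, 0.75)
  pts <- with_seed(99, data.frame(
    lon = stats::runif(1000, -3, -3 + 9 * 0.75 - 1e-9),
    lat = stats::runif(1000, 2, 2 + 7 * 0.75 - 1e-9)
  ))
  got <- cell_index(r, pts$lon, pts$lat)
  # independent oracle: scan every cell's half-open box
  s <- r$cell_size
  for (i in seq_len(nrow(pts))) {
    hit <- NULL
    for (row in 1:7) {
      for (col in 1:9) {
        x0 <- r$x_ll + (col - 1) * s
        y0 <- r$y_ll + (7 - row) * s
        if (pts$lon[i] >= x0 && pts$lon[i] < x0 + s &&
          pts$lat[i] >= y0 && pts$lat[i] < y0 + s) {
          hit <- c(row, col)
        }
      }
    }
    expect_equal(unname(got[i, ]), hit)
  }
})

test_that("occurrence CSVs are validated on read", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(species = "x", longitude = c(1, 2), latitude = c(3, 4)),
    p,
    row.names = FALSE
  )
  expect_silent(df <- read_occurrences(p))
  expect_equal(nrow(df), 2)
  utils::write.csv(data.frame(species = "x", lon = 1, lat = 2), p, row.names = FALSE)
  expect_error(read_occurrences(p), "longitude")
  utils::write.csv(
    data.frame(species = "x", longitude = 500, latitude = 0), p,
    row.names = FALSE
  )
  expect_error(read_occurrences(p), "\\[-180, 180\\)")
})
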