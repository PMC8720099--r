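test_that("ASCII grid write/read round-trips values, nodata and geometry", {
  set.seed(42)
  m <- matrix(rnorm(100), 10, 10)
  m[c(3, 57, 91)] <- NA
  g <- raster_grid(m, origin = c(1234.5, 987.25), cell_size = 30)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_raster(g, path)
  g2 <- read_ascii_raster(path)
  expect_identical(g2$values, g$values)
  expect_identical(g2$origin, g$origin)
  expect_identical(g2$cell_size, g$cell_size)
  expect_true(all(is.na(g2$values[c(3, 57, 91)])))
})

test_that("rasters with rectangular cells are rejected with a clear error", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "dx 10", "dy 20", "NODATA_value -9999", "1 2"), path)
  expect_error(read_ascii_raster(path), "square cells")
})

test_that("world/cell mapping is the identity on centres; edges go to the larger index", {
  g <- test_grid(matrix(0, 4, 5), cell_size = 10)
  rr <- rep(1:4, times = 5); cc <- rep(1:5, each = 4)
  ctr <- cell_center(g, rr, cc)
  back <- world_to_cell(g, ctr$x, ctr$y)
  expect_identical(back$row, rr)
  expect_identical(back$col, cc)
  # x = 10 is the shared edge between columns 1 and 2 -> column 2;
  # y = 30 the edge between rows 1 and 2 -> row 2
  edge <- world_to_cell(g, 10, 30)
  expect_identical(c(edge$row, edge$col), c(2L, 2L))
  expect_true(is.na(world_to_cell(g, -1, 5)$row))
})

test_that("band indices follow their printed formulas and propagate nodata", {
  nir <- test_grid(matrix(c(0.8, 0.5, 0, NA), 2, 2))
  red <- test_grid(matrix(c(0.2, 0.5, 0, 0.3), 2, 2))
  out <- ndvi(nir, red)
  expect_equal(out$values[1, 1], 0.6)
  expect_equal(out$values[2, 1], 0)      # nir == red
  expect_true(is.na(out$values[1, 2]))   # 0/0
  expect_true(is.na(out$values[2, 2]))   # nodata input

  r <- test_grid(matrix(0.3, 2, 2)); b <- test_grid(matrix(0.1, 2, 2))
  expect_equal(rbvi(r, b)$values, matrix(0.5, 2, 2))
  expect_equal(rbvi(b, b)$values, matrix(0, 2, 2))

  set.seed(1)
  a <- test_grid(matrix(runif(100), 10)); b2 <- test_grid(matrix(runif(100), 10))
  v <- ndvi(a, b2)$values
  expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
  expect_error(ndvi(a, test_grid(matrix(1, 5, 5))), "co-registered")
})

test_that("tpi matches hand evaluation and is translation invariant", {
  flat <- test_grid(matrix(7, 6, 6))
  expect_equal(tpi(flat)$values, matrix(0, 6, 6))

  peak <- matrix(0, 5, 5); peak[3, 3] <- 4
  tp <- tpi(test_grid(peak), window_radius = 1)
  expect_equal(tp$values[3, 3], 4)          # peak minus flat neighbours
  expect_equal(tp$values[2, 2], -4 / 8)     # neighbour sees the peak in its window

  ramp <- test_grid(matrix(rep(1:8, each = 6), 6, 8))
  tr <- tpi(ramp)$values
  expect_equal(tr[2:5, 2:7], matrix(0, 4, 6))   # symmetric window on a ramp

  set.seed(2)
  dem <- matrix(rnorm(48), 6, 8)
  expect_equal(tpi(test_grid(dem))$values, tpi(test_grid(dem + 100))$values)
  expect_error(tpi(test_grid(matrix(0, 3, 3)), window_radius = 2), "larger than the grid")
})

test_that("plot extraction handles points, polygons, reducers and nodata", {
  g <- test_grid(matrix(5, 4, 4))
  pts <- tibble::tibble(plot_id = "p1", x = 15, y = 25)
  expect_equal(extract_plot_values(pts, g)$value, 5)

  # one row of cells valued 1, 2, 3; polygon covering all three centres
  g3 <- test_grid(matrix(c(1, 2, 3), 1, 3), cell_size = 10)
  poly <- tibble::tibble(plot_id = "q",
                         geometry = list(cbind(c(0, 30, 30, 0), c(0, 0, 10, 10))))
  expect_equal(extract_plot_values(poly, g3)$value, 2)
  expect_equal(extract_plot_values(poly, g3, reducer = "center")$value, 2)

  gna <- test_grid(matrix(NA_real_, 2, 2))
  expect_error(extract_plot_values(tibble::tibble(plot_id = "x", x = 50, y = 5), gna),
               "outside")
  pin <- tibble::tibble(plot_id = "na",
                        geometry = list(cbind(c(0, 20, 20, 0), c(0, 0, 20, 20))))
  expect_error(extract_plot_values(pin, gna), "nodata")
})
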