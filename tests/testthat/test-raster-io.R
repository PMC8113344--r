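test_that("grid coordinate mapping is pixel-center referenced and invertible", {
  g <- grid_spec(10, 8, pixel_size = 30, origin_x = 1000, origin_y = 2000)
  ctr <- pixel_center(g, 0, 0)
  expect_equal(unname(ctr[1, ]), c(1015, 1985))
  rc <- coord_to_pixel(g, ctr[, "x"], ctr[, "y"])
  expect_equal(unname(rc[1, ]), c(0L, 0L))
  # corners map back; outside points are NA
  rc2 <- coord_to_pixel(g, c(1000 + 8 * 30 - 1, 999), c(2000 - 10 * 30 + 1, 2001))
  expect_equal(unname(rc2[1, ]), c(9L, 7L))
  expect_true(all(is.na(rc2[2, ])))
  expect_error(grid_spec(0, 5), "n_rows")
})

test_that("rasters round-trip through TIFF + sidecar, values and NA intact", {
  g <- grid_spec(7, 5)
  set.seed(1)
  layers <- list(a = matrix(rnorm(35, 0, 10), 7, 5),
                 b = matrix(runif(35, -30, -5), 7, 5),
                 const = matrix(3.5, 7, 5))
  layers$a[c(3, 9)] <- NA
  path <- tempfile(fileext = ".tif")
  write_raster(layers, path, g)
  r <- read_raster(path)
  expect_equal(names(r$layers), c("a", "b", "const"))
  for (nm in names(layers))
    expect_equal(r$layers[[nm]], layers[[nm]], tolerance = 1e-6)
  expect_identical(which(is.na(r$layers$a)), which(is.na(layers$a)))
  expect_identical(format(r$grid), format(g))
})

test_that("scene IO preserves bands, mask, and metadata", {
  g <- grid_spec(4, 4)
  s <- px_scene(c(0.1, 0.2, 0.15, 0.4, 0.25, 0.2), grid = g, tir = 0.3)
  s$mask[1, 1] <- MASK_CODES[["cloud"]]
  s$mask[2, 2] <- MASK_CODES[["nodata"]]
  path <- tempfile(fileext = ".tif")
  write_scene(s, path)
  s2 <- read_scene(path)
  expect_equal(names(s2$bands), names(s$bands))
  expect_equal(s2$bands$Bnir, s$bands$Bnir, tolerance = 1e-6)
  expect_identical(s2$mask, s$mask)
  expect_equal(s2$date, s$date)
  expect_identical(s2$sensor, "OLI")
})

test_that("nodata sentinel pixels become masked on read", {
  g <- grid_spec(3, 3)
  b <- matrix(0.2, 3, 3)
  b[c(1, 5, 9)] <- -9999
  path <- tempfile(fileext = ".tif")
  write_raster(list(Bblue = b), path, g)
  s <- read_scene(path, nodata = -9999)
  expect_identical(sum(s$mask == MASK_CODES[["nodata"]]), 3L)
  expect_identical(sum(is.na(s$bands$Bblue)), 3L)
})

test_that("band_map out of range and unknown names error", {
  g <- grid_spec(2, 2)
  path <- tempfile(fileext = ".tif")
  write_raster(list(x = matrix(0.1, 2, 2), y = matrix(0.2, 2, 2)), path, g)
  expect_error(read_scene(path, band_map = c(Bblue = 9L)), "out of range")
  expect_error(read_scene(path, band_map = c(Bmagenta = 1L)), "band set")
  s <- read_scene(path, band_map = c(Bblue = 1L, Bred = 2L))
  expect_equal(s$bands$Bred[1, 1], 0.2, tolerance = 1e-6)
})

test_that("label rasters round-trip with a nodata sentinel", {
  g <- grid_spec(2, 2)
  lab <- label_raster(matrix(c(1L, 2L, 3L, 4L), 2, 2), g, level = 1L)
  path <- tempfile(fileext = ".tif")
  write_label_raster(lab, path)
  back <- read_label_raster(path)
  expect_identical(back$values, lab$values)
  expect_identical(back$level, 1L)
  expect_equal(as.vector(table(back$values)), rep(1L, 4), ignore_attr = TRUE)
  # all-nodata raster: every stored pixel equals the sentinel
  lab2 <- label_raster(matrix(NA_integer_, 2, 2), g)
  path2 <- tempfile(fileext = ".tif")
  write_label_raster(lab2, path2, sentinel = 0L)
  raw <- read_raster(path2)
  expect_true(all(round(raw$layers[[1]]) == 0))
  expect_true(all(is.na(read_label_raster(path2)$values)))
  # sentinel colliding with a class id refuses to write
  expect_error(write_label_raster(lab, tempfile(), sentinel = 2L), "collides")
})

test_that("CSV samples validate classes and grid bounds", {
  tax <- default_taxonomy()
  g <- grid_spec(10, 10)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(row = 0:4, col = 2:6,
                       class = c("Residence", "Cropland", "Wetland",
                                 "OpenWater", "Aquaculture")),
            f, row.names = FALSE)
  pts <- read_samples(f, tax, grid = g, level = 1L, year = 2020)
  expect_identical(nrow(pts), 5L)
  expect_identical(pts$class_id, c(1L, 3L, 8L, 9L, 10L))
  write.csv(data.frame(row = 0, col = 0, class = "SnowIce"), f,
            row.names = FALSE)
  expect_error(read_samples(f, tax, grid = g, level = 1L), "SnowIce")
  write.csv(data.frame(row = 99, col = 0, class = "Residence"), f,
            row.names = FALSE)
  expect_error(read_samples(f, tax, grid = g, level = 1L), "outside")
})

test_that("GeoJSON polygons rasterize to interior pixel centers", {
  tax <- default_taxonomy()
  g <- grid_spec(10, 10, pixel_size = 30, origin_x = 0, origin_y = 300)
  # square spanning exactly the centers of pixels (rows 1-2, cols 1-2):
  # centers at x,y in {45, 75}
  ring <- list(list(30, 250), list(100, 250), list(100, 190), list(30, 190),
               list(30, 250))
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(class = "Cropland", year = 2020),
         geometry = list(type = "Polygon", coordinates = list(ring)))))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  pts <- read_samples(f, tax, grid = g, level = 1L)
  expect_identical(nrow(pts), 4L)
  expect_setequal(paste(pts$row, pts$col), c("2 1", "2 2", "3 1", "3 2"))
  expect_true(all(pts$class_id == 3L))
})

test_that("grid mismatch raises rather than resampling", {
  a <- grid_spec(4, 4); b <- grid_spec(4, 5)
  expect_error(check_same_grid(a, b), "grid mismatch")
  m1 <- label_raster(matrix(1L, 4, 4), a)
  m2 <- label_raster(matrix(1L, 4, 5), b)
  expect_error(change_frequency(list(m1, m2)), "grid mismatch")
})
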