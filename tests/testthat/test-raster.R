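make_feature_table <- function(cells, metric = "Hmax", cell_size = 10) {
  # minimal feature table: list of (i, j, value)
  ft <- data.table::data.table(cell_i = vapply(cells, `[[`, 0, 1),
                               cell_j = vapply(cells, `[[`, 0, 2))
  ft[, cell_i := as.integer(cell_i)][, cell_j := as.integer(cell_j)]
  for (m in als_metric_names()) ft[, (m) := NA_real_]
  ft[, (metric) := vapply(cells, `[[`, 0, 3)]
  ft[, `:=`(cell_x = (cell_i + 0.5) * cell_size,
            cell_y = (cell_j + 0.5) * cell_size)]
  ft
}

test_that("rasterize_features places centroids and nodata correctly", {
  lay <- rasterize_features(make_feature_table(list(c(0, 0, 7))), "Hmax")
  expect_identical(dim(lay$values), c(1L, 1L))
  expect_equal(lay$values[1, 1], 7)
  expect_equal(lay$origin, c(0, 10))

  # an L-shape leaves one nodata cell, distinguishable from 0
  lay2 <- rasterize_features(
    make_feature_table(list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 3))), "Hmax")
  expect_identical(dim(lay2$values), c(2L, 2L))
  expect_equal(lay2$values[2, 1], 1)   # cell (0,0): south-west
  expect_equal(lay2$values[2, 2], 0)   # a true zero survives
  expect_true(is.na(lay2$values[1, 2]))
})

test_that("adjacent tile tables merge seamlessly and order-independently", {
  left <- make_feature_table(lapply(0:9, function(i) c(i, 0, i)))
  right <- make_feature_table(lapply(10:19, function(i) c(i, 0, i)))
  a <- rasterize_features(list(left, right), "Hmax")
  b <- rasterize_features(list(right, left), "Hmax")
  expect_identical(dim(a$values), c(1L, 20L))
  expect_equal(a$values[1, ], as.numeric(0:19))
  expect_identical(a, b)
})

test_that("conflicting duplicate cells raise an error naming the cell", {
  t1 <- make_feature_table(list(c(2, 3, 1)))
  t2 <- make_feature_table(list(c(2, 3, 2)))
  expect_error(rasterize_features(list(t1, t2), "Hmax"), "\\(2, 3\\)")
  # agreeing duplicates are fine
  expect_equal(rasterize_features(list(t1, t1), "Hmax")$values[1, 1], 1)
})

test_that("GeoTIFF round trip preserves values, nodata, transform and CRS", {
  set.seed(201)
  vals <- matrix(runif(12 * 9, -50, 50), nrow = 9)
  vals[sample(length(vals), 10)] <- NA
  vals[1, 1] <- 0
  lay <- raster_layer(vals, origin = c(120350, 487210), cell_size = 10,
                      crs = "EPSG:28992", nodata = -9999)
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(lay, f)
  r <- read_geotiff(f)
  expect_identical(dim(r$values), dim(vals))
  expect_identical(is.na(r$values), is.na(vals))
  expect_equal(r$values, vals, tolerance = 1e-6)  # float32 storage
  expect_identical(r$origin, lay$origin)
  expect_identical(r$cell_size, 10)
  expect_identical(r$crs, "EPSG:28992")
  expect_identical(r$nodata, -9999)
  # reading the file back twice is bit-stable
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(r, f2)
  expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))
})

test_that("the written TIFF is readable by an independent TIFF decoder", {
  skip_if_not_installed("tiff")
  vals <- matrix(as.numeric(1:6), nrow = 2, byrow = TRUE)
  lay <- raster_layer(vals, origin = c(0, 20), cell_size = 10)
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(lay, f)
  px <- suppressWarnings(tiff::readTIFF(f))
  expect_equal(matrix(as.numeric(px), nrow = 2), vals)
})

test_that("mask burn-in uses the cell-centre rule over the polygon union", {
  template <- raster_layer(matrix(NA_real_, 4, 4), origin = c(0, 40),
                           cell_size = 10)
  # full cover of cell (0,0) -> 1
  sq <- function(x0, y0, x1, y1)
    list(cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0)))
  m1 <- build_mask(list(sq(0, 0, 10, 10)), template)
  expect_equal(m1$values[4, 1], 1)
  expect_equal(sum(m1$values), 1)
  # touching only a corner, not the centre -> 0
  m2 <- build_mask(list(sq(0, 0, 4, 4)), template)
  expect_equal(sum(m2$values), 0)
  # overlapping polygons still mask (union, not parity)
  m3 <- build_mask(list(sq(0, 0, 10, 10), sq(2, 2, 12, 12)), template)
  expect_equal(m3$values[4, 1], 1)
  expect_true(all(m3$values %in% c(0, 1)))
  # a hole in a polygon unmasks the centre it covers
  donut <- list(sq(0, 0, 30, 30)[[1]], sq(12, 12, 18, 18)[[1]])
  m4 <- build_mask(list(donut), template)
  expect_equal(m4$values[3, 2], 0)   # cell centred at (15, 15)
  expect_equal(m4$values[4, 1], 1)
  # empty polygon set -> all-zero mask, with a message
  expect_message(m0 <- build_mask(list(), template), "empty polygon")
  expect_equal(sum(m0$values), 0)
  # the any-overlap option catches the corner case the centre rule misses
  m5 <- build_mask(list(sq(0, 0, 4, 4)), template, rule = "any")
  expect_equal(m5$values[4, 1], 1)
})

test_that("apply_mask is idempotent and leaves unmasked cells bit-exact", {
  set.seed(202)
  vals <- matrix(runif(25), 5, 5)
  lay <- raster_layer(vals, origin = c(0, 50), cell_size = 10)
  mask <- raster_layer(matrix(as.numeric(runif(25) < 0.4), 5, 5),
                       origin = c(0, 50), cell_size = 10)
  masked <- apply_mask(lay, mask)
  expect_identical(is.na(masked$values), mask$values == 1)
  keep <- mask$values == 0
  expect_identical(masked$values[keep], lay$values[keep])
  expect_identical(apply_mask(masked, mask), masked)
  # 12.3 under mask 1 -> nodata; under mask 0 -> 12.3
  one <- raster_layer(matrix(12.3), c(0, 10), 10)
  expect_true(is.na(apply_mask(one, raster_layer(matrix(1), c(0, 10), 10))$values))
  expect_equal(apply_mask(one, raster_layer(matrix(0), c(0, 10), 10))$values[1],
               12.3)
  # grid mismatch is refused
  off <- raster_layer(matrix(0, 5, 5), origin = c(10, 50), cell_size = 10)
  expect_error(apply_mask(lay, off), "align")
})

test_that("GeoJSON polygons parse with tags and drive masking", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(type = "water"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(20, 0),
                                                   list(20, 20), list(0, 20),
                                                   list(0, 0))))),
      list(type = "Feature",
           properties = list(type = "road"),
           geometry = list(type = "MultiPolygon",
                           coordinates = list(list(list(list(30, 30), list(40, 30),
                                                        list(40, 40), list(30, 40),
                                                        list(30, 30)))))))
  )
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  polys <- read_polygons_geojson(f)
  expect_length(polys, 2)
  expect_identical(attr(polys[[1]], "tag"), "water")
  expect_length(read_polygons_geojson(f, types = "water"), 1)
  template <- raster_layer(matrix(NA_real_, 4, 4), origin = c(0, 40),
                           cell_size = 10)
  m <- build_mask(polys, template)
  expect_equal(sum(m$values), 5)  # 2x2 water cells + 1 road cell
})
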