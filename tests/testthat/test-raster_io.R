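# Raster, polygon and table I/O.

test_that("ASCII grid round-trip preserves heights, nodata and resolution", {
  set.seed(1)
  v <- matrix(rnorm(120, 5, 2), 10, 12)
  v[c(3, 50, 99)] <- NA
  r <- height_raster(v, 0.01)
  p <- file.path(tempdir(), "rt.asc")
  write_height_raster(r, p)
  r2 <- read_height_raster(p)
  expect_equal(r2$resolution, 0.01)
  expect_identical(is.na(r2$values), is.na(v))
  expect_equal(r2$values, v, tolerance = 1e-8)
})

test_that("label raster round-trip is lossless", {
  set.seed(2)
  lab <- matrix(sample(0:3, 200, replace = TRUE), 10, 20)
  p <- file.path(tempdir(), "lab.asc")
  write_label_raster(lab, p, resolution = 0.05)
  back <- read_label_raster(p)
  expect_identical(back$labels, matrix(as.integer(lab), 10, 20))
  expect_equal(back$resolution, 0.05)
})

test_that("TIFF reading takes resolution from the sidecar and flags errors", {
  img <- matrix(runif(100), 10, 10)
  p <- file.path(tempdir(), "t.tif")
  tiff::writeTIFF(img, p, bits.per.sample = 32L)
  expect_error(read_height_raster(p), "resolution unknown")
  writeLines(jsonlite::toJSON(list(resolution = 0.01), auto_unbox = TRUE),
             paste0(p, ".json"))
  r <- read_height_raster(p)
  expect_equal(r$resolution, 0.01)
  expect_equal(r$values, img, tolerance = 1e-6)
  # non-square pixels are rejected
  writeLines(jsonlite::toJSON(list(resolution = c(0.01, 0.02))),
             paste0(p, ".json"))
  expect_error(read_height_raster(p), "non-square pixels")
  file.remove(paste0(p, ".json"))
  # multi-band file without a band selection
  arr <- array(runif(300), c(10, 10, 3))
  p3 <- file.path(tempdir(), "t3.tif")
  tiff::writeTIFF(arr, p3, bits.per.sample = 32L)
  expect_error(read_height_raster(p3, resolution = 0.01), "multi-band")
  expect_silent(read_height_raster(p3, resolution = 0.01, band = 2))
  expect_error(read_height_raster(file.path(tempdir(), "absent.tif")), "not found")
})

test_that("polygon masking matches a brute-force point-in-polygon oracle", {
  set.seed(3)
  v <- matrix(rnorm(400), 20, 20)
  r <- height_raster(v, 1)
  tri <- polygon_mask(x = c(2.2, 18.7, 9.1), y = c(2.9, 4.4, 18.2))
  masked <- apply_polygon_mask(r, tri)
  inside_oracle <- matrix(FALSE, 20, 20)
  for (rr in 1:20) for (cc in 1:20)
    inside_oracle[rr, cc] <- oracle_point_in_polygon(cc, rr, tri$x, tri$y)
  expect_identical(!is.na(masked$values), inside_oracle)
  expect_equal(sum(!is.na(masked$values)), sum(inside_oracle))
})

test_that("masking is idempotent, preserves inside cells, keeps nodata holes", {
  set.seed(4)
  v <- matrix(rnorm(400), 20, 20)
  v[5, 5] <- NA # photogrammetric hole inside the field stays nodata
  r <- height_raster(v, 1)
  half <- polygon_mask(x = c(0.5, 10.5, 10.5, 0.5), y = c(0.5, 0.5, 20.5, 20.5))
  m1 <- apply_polygon_mask(r, half)
  expect_true(all(is.na(m1$values[, 11:20])))
  inside <- m1$values[, 1:10]
  expect_identical(inside[!is.na(inside)], v[, 1:10][!is.na(v[, 1:10])])
  expect_true(is.na(m1$values[5, 5]))
  m2 <- apply_polygon_mask(m1, half)
  expect_identical(m2$values, m1$values)
  # full-cover polygon is the identity
  all_poly <- polygon_mask(x = c(0, 21, 21, 0), y = c(0, 0, 21, 21))
  expect_identical(apply_polygon_mask(r, all_poly)$values, r$values)
  # fully outside polygon
  out_poly <- polygon_mask(x = c(100, 110, 105), y = c(100, 100, 110))
  expect_error(apply_polygon_mask(r, out_poly), "empty field region")
})

test_that("polygon constructor validates rings", {
  expect_error(polygon_mask(x = c(1, 2), y = c(1, 2)), "at least 3")
  expect_error(polygon_mask(x = c(0, 2, 2, 0), y = c(0, 2, 0, 2)),
               "self-intersecting")
  # explicitly closed rings are accepted
  p <- polygon_mask(x = c(0, 2, 2, 0, 0), y = c(0, 0, 2, 2, 0))
  expect_length(p$x, 4)
})

test_that("GeoJSON polygons and crown outlines round-trip", {
  gj <- file.path(tempdir(), "field.geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature", properties = NULL,
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(1, 1), c(9, 1), c(9, 9), c(1, 9), c(1, 1))))
  ), auto_unbox = TRUE), gj)
  pm <- read_field_polygon(gj)
  expect_s3_class(pm, "polygon_mask")
  expect_length(pm$x, 4)

  lab <- matrix(0L, 12, 12); lab[3:6, 3:8] <- 1L; lab[9:11, 2:4] <- 2L
  out <- file.path(tempdir(), "outlines.geojson")
  write_crown_outlines(lab, out)
  fc <- jsonlite::fromJSON(out, simplifyVector = FALSE)
  expect_equal(fc$type, "FeatureCollection")
  expect_length(fc$features, 2)
  expect_equal(fc$features[[1]]$geometry$type, "MultiPolygon")
})

test_that("crown and reference tables validate and round-trip", {
  rec <- tibble::tibble(
    tree_id = 1:3, W1_m = c(1, 2, 3), W2_m = c(2, 2, 2), CPA_m2 = c(1.5, 3, 4),
    bbox_row_min = 1L, bbox_row_max = 5L, bbox_col_min = 2L, bbox_col_max = 9L,
    pixel_count = c(10L, 20L, 30L)
  )
  p <- file.path(tempdir(), "crowns.csv")
  write_crown_table(rec, p)
  back <- read_crown_table(p)
  expect_equal(as.data.frame(back), as.data.frame(rec[names(back)]))
  expect_error(write_crown_table(rec[, -2], p), "missing column: W1_m")

  ref <- data.frame(tree_id = 1:2, W1_m = 1:2)
  rp <- file.path(tempdir(), "ref.csv")
  write.csv(ref, rp, row.names = FALSE)
  expect_error(read_reference_table(rp), "missing column: W2_m")
  ref$W2_m <- 2:3
  write.csv(ref, rp, row.names = FALSE)
  expect_s3_class(read_reference_table(rp), "tbl_df")
})
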