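test_that("ASCII grid write/read round trip is lossless", {
  g <- grid_spec(5, 7, xll = -12.25, yll = 3.5, cellsize = 0.125,
                 crs_label = "EPSG:4326", nodata = -9999)
  set.seed(21)
  m <- matrix(runif(35, 150, 330), 5, 7)
  m[2, 3] <- NA
  m[5, 1] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(m, path, grid = g)
  back <- read_ascii_grid(path)
  expect_identical(stack_layer(back, 1), m)
  expect_equal(back$grid$xll, g$xll)
  expect_equal(back$grid$yll, g$yll)
  expect_equal(back$grid$cellsize, g$cellsize)
  expect_equal(back$grid$n_rows, g$n_rows)
  expect_identical(back$grid$crs_label, "EPSG:4326")
})

test_that("Kelvin enforcement refuses Celsius-looking files", {
  g <- grid_spec(2, 2)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(matrix(c(25, 30, 18, 22), 2, 2), path, grid = g)
  expect_error(read_ascii_grid(path, check_kelvin = TRUE),
               class = "thermdecay_data_error")
  # scaled-integer input is accepted with the right scale factor
  ok <- read_ascii_grid(path, check_kelvin = TRUE, scale = 10)
  expect_equal(stack_layer(ok, 1)[1, 1], 250)
})

test_that("regrid preserves constants in both directions", {
  fine <- raster_stack(matrix(7, 8, 8), grid_spec(8, 8, cellsize = 1))
  coarse_g <- grid_spec(2, 2, cellsize = 4)
  up <- regrid(fine, coarse_g)
  expect_true(all(stack_layer(up, 1) == 7))
  down <- regrid(up, fine$grid)
  expect_true(all(stack_layer(down, 1) == 7))
})

test_that("block-mean upscaling averages valid pixels only", {
  g2 <- grid_spec(2, 2, cellsize = 1)
  target <- grid_spec(1, 1, cellsize = 2)
  full <- raster_stack(matrix(c(280, 290, 300, 310), 2, 2), g2)
  expect_equal(stack_layer(regrid(full, target), 1)[1, 1], 295)
  holed <- raster_stack(matrix(c(280, NA, 290, 310), 2, 2), g2)
  expect_equal(stack_layer(regrid(holed, target), 1)[1, 1],
               mean(c(280, 290, 310)))
  empty <- raster_stack(matrix(NA_real_, 2, 2), g2)
  expect_true(is.na(stack_layer(regrid(empty, target), 1)[1, 1]))
})

test_that("regrid round trip on block-constant fields is the identity", {
  blocks <- matrix(rep(c(1, 2, 3, 4), each = 2), 4, 4)[, c(1, 1, 2, 2)] * 100
  fine <- raster_stack(blocks, grid_spec(4, 4, cellsize = 1))
  coarse <- regrid(fine, grid_spec(2, 2, cellsize = 2))
  back <- regrid(coarse, fine$grid)
  expect_equal(stack_layer(back, 1), blocks)
})

test_that("upscaling conserves the global mean over valid areas", {
  set.seed(8)
  vals <- matrix(runif(144, 200, 320), 12, 12)
  fine <- raster_stack(vals, grid_spec(12, 12, cellsize = 1))
  up <- regrid(fine, grid_spec(3, 3, cellsize = 4))
  expect_equal(mean(stack_layer(up, 1)), mean(vals), tolerance = 1e-12)
})

test_that("nearest-neighbor downscaling picks the containing source pixel", {
  src <- raster_stack(matrix(c(1, 3, 2, 4), 2, 2),
                      grid_spec(2, 2, cellsize = 2))
  down <- regrid(src, grid_spec(4, 4, cellsize = 1))
  expect_equal(stack_layer(down, 1),
               matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4),
                      4, 4))
})

test_that("non-overlapping grids are rejected", {
  src <- raster_stack(matrix(1, 2, 2), grid_spec(2, 2, xll = 0, yll = 0))
  far <- grid_spec(2, 2, xll = 100, yll = 100)
  expect_error(regrid(src, far), class = "thermdecay_data_error")
})

test_that("threshold masking keeps strictly-above pixels and counts them", {
  g <- grid_spec(1, 3)
  stack <- raster_stack(array(rep(c(400, 500, 600), 2), c(1, 3, 2)), g,
                        time_labels = c("a", "b"))
  map <- raster_stack(matrix(c(50, 100, 150), 1, 3), g)
  out <- mask_by_threshold(stack, map, threshold = 100)
  expect_true(all(is.na(out$values[, 1:2, ])))   # 50 and the boundary 100
  expect_false(anyNA(out$values[, 3, ]))
  expect_equal(attr(out, "n_retained"), 1)
  # -Inf threshold is the identity
  ident <- mask_by_threshold(stack, map, threshold = -Inf)
  expect_equal(ident$values, stack$values)
  # all-masked input
  none <- mask_by_threshold(stack, map, threshold = 1e9)
  expect_true(all(is.na(none$values)))
  expect_equal(attr(none, "n_retained"), 0)
  bad <- raster_stack(matrix(1, 2, 2), grid_spec(2, 2))
  expect_error(mask_by_threshold(stack, bad),
               class = "thermdecay_data_error")
})

test_that("rdk_annual_map applies the estimator per pixel and year", {
  sc <- tiny_scene(t_ambient = 0)
  st <- scene_stacks(sc)
  res <- rdk_annual_map(st$day, st$night, min_pairs = 5)
  expect_equal(dim(res$rdk)[3], 3)
  expect_equal(stack_layer(res$rdk, 1), sc$truth_k, tolerance = 1e-13)
  expect_true(all(stack_layer(res$n_pairs, 1) == 12))

  # Swapping day and night negates the map
  swapped <- rdk_annual_map(st$night, st$day, min_pairs = 5)
  expect_equal(stack_layer(swapped$rdk, 1), -stack_layer(res$rdk, 1))

  # A pixel masked all year is nodata with n_pairs = 0
  day <- st$day
  night <- st$night
  day$values[1, 1, ] <- NA
  night$values[1, 1, ] <- NA
  res2 <- rdk_annual_map(day, night, min_pairs = 5)
  expect_true(all(is.na(res2$rdk$values[1, 1, ])))
  expect_true(all(res2$n_pairs$values[1, 1, ] == 0))

  # Misaligned stacks error
  other <- raster_stack(array(300, c(2, 2, 1)), grid_spec(2, 2))
  expect_error(rdk_annual_map(st$day, other),
               class = "thermdecay_data_error")
})

test_that("stacks convert to tidy tibbles with pixel-center coordinates", {
  g <- grid_spec(2, 2, xll = 10, yll = 20, cellsize = 2)
  st <- raster_stack(matrix(1:4, 2, 2), g)
  df <- tibble::as_tibble(st)
  expect_equal(nrow(df), 4)
  top_left <- df[df$row == 1 & df$col == 1, ]
  expect_equal(top_left$x, 11)   # xll + cell/2
  expect_equal(top_left$y, 23)   # yll + (2 - 1 + 0.5) * 2
  expect_equal(top_left$value, 1)
})
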