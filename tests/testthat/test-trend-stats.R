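test_that("mann_kendall matches its textbook values on a monotone series", {
  mk <- mann_kendall(c(1, 2, 3, 4), min_n = 4)
  expect_equal(mk$s, 6)
  expect_equal(mk$var_s, 8.666666666666666, tolerance = 1e-12)
  expect_equal(mk$z, 1.6984155512168937, tolerance = 1e-12)
  expect_equal(mk$p_value, 0.08942935902899353, tolerance = 1e-12)
  expect_equal(mk$n, 4)
})

test_that("mann_kendall handles constants, reversal and missing values", {
  const <- mann_kendall(rep(5, 12))
  expect_equal(const$s, 0)
  expect_equal(const$z, 0)
  expect_equal(const$p_value, 1)

  set.seed(14)
  x <- rnorm(20)
  fwd <- mann_kendall(x)
  rev <- mann_kendall(rev(x))
  expect_equal(rev$s, -fwd$s)
  expect_equal(rev$p_value, fwd$p_value)

  # NA dropped with positions; short series give a missing result
  gappy <- mann_kendall(c(1, NA, 2, NA, 3), min_n = 3)
  expect_equal(gappy$n, 3)
  expect_equal(gappy$s, 3)
  short <- mann_kendall(c(1, 2, 3), min_n = 10)
  expect_true(is.na(short$p_value))
  expect_equal(short$n, 3)
})

test_that("mann_kendall agrees with the brute-force oracle incl. ties", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:50, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n) * sample(c(0, 1), 1)
    mk <- mann_kendall(x, min_n = 4)
    or <- mk_brute(x)
    expect_identical(mk$s, or$s)
    expect_equal(mk$var_s, or$var_s, tolerance = 1e-12)
    expect_equal(mk$z, or$z, tolerance = 1e-12)
    expect_equal(mk$p_value, or$p_value, tolerance = 1e-12)
  }
})

test_that("tie correction shrinks the variance, no ties leaves it alone", {
  tied <- c(1, 2, 2, 3, 3, 3, 4)
  with_tc <- mann_kendall(tied, min_n = 5)
  without_tc <- mann_kendall(tied, min_n = 5, tie_correction = FALSE)
  expect_lt(with_tc$var_s, without_tc$var_s)
  untied <- c(1.1, 2.7, 0.3, 5.9, 4.2, 3.8)
  expect_equal(mann_kendall(untied, min_n = 5)$var_s,
               mann_kendall(untied, min_n = 5,
                            tie_correction = FALSE)$var_s)
})

test_that("classify_trend maps sign and p into the five classes", {
  expect_equal(as.character(classify_trend(20, p = 0.03)),
               "increasing_p05")
  expect_equal(as.character(classify_trend(20, p = 0.07)),
               "increasing_p10")
  expect_equal(as.character(classify_trend(-20, p = 0.03)),
               "decreasing_p05")
  expect_equal(as.character(classify_trend(-20, p = 0.07)),
               "decreasing_p10")
  expect_equal(as.character(classify_trend(20, p = 0.5)), "none")
  expect_equal(as.character(classify_trend(-20, p = 0.5)), "none")
  expect_true(is.na(classify_trend(NA_real_, p = NA_real_)))
  mk <- mann_kendall(1:12)
  expect_equal(as.character(classify_trend(mk)), "increasing_p05")
})

test_that("trend_map classifies injected trends and rejects thin stacks", {
  g <- grid_spec(4, 4)
  years <- 2003:2017
  set.seed(31)
  # Half the pixels get a strong positive trend, half none
  arr <- array(rnorm(4 * 4 * 15), c(4, 4, 15))
  for (j in seq_along(years)) {
    arr[, 1:2, j] <- arr[, 1:2, j] + 0.5 * j
  }
  stack <- raster_stack(arr, g, as.character(years))
  res <- trend_map(stack, min_n = 10)
  cls <- stack_layer(res$classes, 1)
  expect_true(all(cls[, 1:2] == 5))          # increasing_p05
  expect_equal(sum(res$counts$n), 16)
  expect_equal(res$counts$n[res$counts$class == "increasing_p05"],
               sum(cls == 5))
  # Inversion recodes as vegetation trends
  inv <- trend_map(stack, min_n = 10, invert = TRUE)
  expect_true(all(stack_layer(inv$classes, 1)[, 1:2] == 1))
  # Single layer errors
  one <- raster_stack(arr[, , 1, drop = FALSE], g, "2003")
  expect_error(trend_map(one, min_n = 10), class = "thermdecay_data_error")
})

test_that("scene-level trend detection is calibrated end to end", {
  # Zero-trend scene: p<0.05 detections near the nominal type-I level.
  # With T_a = 285 K the estimator compresses decay-rate signals ~15-fold
  # (see approximation_bias), so the injected slope is calibrated in truth
  # units: 3e-4 /hr/yr maps to ~0.3 of the annual noise floor per year.
  base <- list(n_rows = 32, n_cols = 32, years = 2003:2017,
               n_composites = 46, noise_sd = 1)
  null_scene <- do.call(make_scene, c(base, seed = 123))
  st <- scene_stacks(null_scene)
  annual <- rdk_annual_map(st$day, st$night, min_pairs = 10)
  res <- trend_map(annual$rdk, min_n = 10)
  cls <- stack_layer(res$classes, 1)
  false_rate <- mean(cls %in% c(1, 5))
  expect_gte(false_rate, 0.03)
  expect_lte(false_rate, 0.07)

  trend_scene <- do.call(make_scene,
                         c(base, trend_slope = 3e-4, seed = 124))
  st2 <- scene_stacks(trend_scene)
  annual2 <- rdk_annual_map(st2$day, st2$night, min_pairs = 10)
  res2 <- trend_map(annual2$rdk, min_n = 10)
  detected <- mean(stack_layer(res2$classes, 1) == 5)
  expect_gte(detected, 0.9)
})

test_that("RMA regression matches the closed form on linear data", {
  d <- tibble::tibble(x = c(-3, 1, 2, 5, 9), y = 2 * c(-3, 1, 2, 5, 9) + 1)
  fit <- rma_regression(d, x, y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$pearson_r, 1)

  neg <- tibble::tibble(x = c(-2, 0, 1, 4), y = -3 * c(-2, 0, 1, 4))
  fitn <- rma_regression(neg, x, y)
  expect_equal(fitn$slope, -3)
  expect_equal(fitn$intercept, 0, tolerance = 1e-12)

  expect_error(rma_regression(d[1:2, ], x, y),
               class = "thermdecay_data_error")
  expect_error(rma_regression(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               class = "thermdecay_data_error")
})

test_that("RMA is symmetric under axis swap and scale-equivariant", {
  set.seed(7)
  d <- tibble::tibble(x = rnorm(60), y = 1.4 * rnorm(60) + 0.5)
  ab <- rma_regression(d, x, y)
  ba <- rma_regression(d, y, x)
  expect_equal(ab$slope, 1 / ba$slope, tolerance = 1e-12)
  scaled <- rma_regression(dplyr::mutate(d, y = 10 * y), x, y)
  expect_equal(scaled$slope, 10 * ab$slope, tolerance = 1e-12)
  # slope sign follows the correlation sign
  expect_equal(sign(ab$slope), sign(ab$pearson_r))
  # tidy/glance expose the coefficients
  expect_equal(tidy(ab)$estimate, c(ab$intercept, ab$slope))
  expect_equal(glance(ab)$n, 60)
})

test_that("correlation tables are symmetric with unit diagonal", {
  set.seed(12)
  d <- tibble::tibble(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  d$b[1:10] <- NA
  ct <- correlation_table(d)
  expect_equal(ct$pearson, t(ct$pearson))
  expect_equal(ct$spearman, t(ct$spearman))
  expect_equal(diag(ct$pearson), c(a = 1, b = 1, c = 1))
  expect_true(all(abs(ct$pearson) <= 1, na.rm = TRUE))
  # pairwise-complete: a-b entry uses the 70 complete rows
  expect_equal(ct$n["a", "b"], 70)
  expect_equal(ct$n["a", "c"], 80)
})

test_that("Spearman catches monotone nonlinear links Pearson misses", {
  x <- seq(0.1, 4, length.out = 50)
  ct <- correlation_table(tibble::tibble(x = x, y = exp(x)))
  expect_equal(ct$spearman["x", "y"], 1)
  expect_lt(ct$pearson["x", "y"], 1)
})

test_that("Spearman equals Pearson on ranks (oracle)", {
  set.seed(4)
  x <- rnorm(40)
  y <- x + rnorm(40)
  ct <- correlation_table(tibble::tibble(x = x, y = y))
  expect_equal(ct$spearman["x", "y"], cor(rank(x), rank(y)),
               tolerance = 1e-12)
})

test_that("absolute-value convention and sparse pairs are honored", {
  d <- tibble::tibble(latitude = c(-30, -10, 10, 30), v = c(3, 1, 1, 3))
  ct <- correlation_table(d, absolute = "latitude")
  expect_equal(ct$pearson["latitude", "v"], 1)
  # fewer than 3 jointly valid pixels -> missing entry
  d2 <- tibble::tibble(a = c(1, 2, 5, NA), b = c(NA, NA, 1, 2),
                       c = c(1, 2, 3, 4))
  ct2 <- correlation_table(d2)
  expect_true(is.na(ct2$pearson["a", "b"]))
  expect_false(is.na(ct2$pearson["a", "c"]))
})
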