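#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test on an ordered series: the statistic
#' `S = sum_{i<j} sign(x_j - x_i)` counts concordant minus discordant
#' time-ordered pairs. Under the no-trend null, S is asymptotically normal
#' with tie-corrected variance
#' `Var(S) = [n(n-1)(2n+5) - sum_g t_g(t_g-1)(2t_g+5)] / 18`,
#' where `t_g` are the sizes of tied groups. The Z score applies the
#' standard +/-1 continuity correction (`Z = 0` when `S = 0`) and the
#' p-value is two-sided from the normal approximation.
#'
#' Missing values are dropped (with their time positions — gaps are allowed
#' because the remaining values keep their relative order).
#'
#' @param x Ordered numeric series (e.g. one annual value per year).
#' @param min_n Minimum series length after dropping `NA` (default 10); a
#'   shorter series yields a missing result rather than an error, so
#'   per-pixel maps can record data-poor pixels.
#' @param continuity Apply the +/-1 continuity correction (default `TRUE`).
#' @param tie_correction Apply the tie term of the variance (default
#'   `TRUE`).
#' @return An object of class `mk_test`: `s` (integer statistic), `var_s`,
#'   `z`, `p_value` (two-sided), `n` (values used). When `n < min_n` the
#'   numeric fields are `NA` but `n` is still recorded.
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10), min_n = 10)
#' @export
mann_kendall <- function(x, min_n = 10, continuity = TRUE,
                         tie_correction = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  out <- structure(list(s = NA_real_, var_s = NA_real_, z = NA_real_,
                        p_value = NA_real_, n = n,
                        continuity = continuity,
                        tie_correction = tie_correction),
                   class = "mk_test")
  if (n < min_n) return(out)

  # Signed pair count via pairwise differences (n <= a few hundred here).
  d <- sign(outer(x, x, "-"))
  s <- sum(d[lower.tri(d)])

  var_s <- n * (n - 1) * (2 * n + 5) / 18
  if (tie_correction) {
    t_g <- table(x)
    t_g <- t_g[t_g > 1]
    if (length(t_g) > 0) {
      var_s <- var_s - sum(t_g * (t_g - 1) * (2 * t_g + 5)) / 18
    }
  }

  z <- if (var_s <= 0) 0 else if (s > 0) {
    (s - if (continuity) 1 else 0) / sqrt(var_s)
  } else if (s < 0) {
    (s + if (continuity) 1 else 0) / sqrt(var_s)
  } else 0
  p <- if (var_s <= 0 && s == 0) 1 else 2 * pnorm(-abs(z))

  out$s <- s
  out$var_s <- var_s
  out$z <- z
  out$p_value <- min(p, 1)
  out
}

#' @export
print.mk_test <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %s, Var(S) = %s, Z = %s, p = %s (n = %d)\n",
              format(x$s), format(x$var_s), format(signif(x$z, 4)),
              format(signif(x$p_value, 4)), x$n))
  invisible(x)
}

#' @rdname mann_kendall
#' @param data Not used (for generic consistency); see `x`.
#' @export
tidy.mk_test <- function(x, ...) {
  tibble::tibble(s = x$s, var_s = x$var_s, z = x$z, p_value = x$p_value,
                 n = x$n)
}

#' @export
glance.mk_test <- function(x, ...) tidy.mk_test(x)

#' Ordered trend class levels
#'
#' Five classes combining trend direction with two significance bands:
#' p < 0.05 (high) and 0.05 <= p < 0.1 (moderate). For the decay rate index
#' an *increasing* class is interpreted as *decreasing* vegetation (loss of
#' thermal mass), and vice versa.
#' @export
trend_class_levels <- c("decreasing_p05", "decreasing_p10", "none",
                        "increasing_p10", "increasing_p05")

#' Classify a Mann-Kendall result into significance classes
#'
#' @param mk An `mk_test` result, or a numeric vector of S statistics when
#'   `p` is given.
#' @param p Two-sided p-values matching `mk` when `mk` is numeric.
#' @param p_high,p_moderate Significance thresholds (defaults 0.05, 0.1).
#' @return A factor with levels [trend_class_levels]; `NA` for missing
#'   results.
#' @examples
#' classify_trend(mann_kendall(1:12, min_n = 10))
#' classify_trend(c(20, -20, 3), p = c(0.03, 0.07, 0.5))
#' @export
classify_trend <- function(mk, p = NULL, p_high = 0.05, p_moderate = 0.1) {
  if (inherits(mk, "mk_test")) {
    s <- mk$s
    p <- mk$p_value
  } else {
    s <- mk
    if (is.null(p)) {
      abort("Give `p` when `mk` is a plain S vector.",
            class = "thermdecay_config_error")
    }
  }
  lab <- rep(NA_character_, length(s))
  known <- !is.na(s) & !is.na(p)
  lab[known] <- "none"
  up <- known & s > 0
  dn <- known & s < 0
  lab[up & p < p_moderate] <- "increasing_p10"
  lab[up & p < p_high] <- "increasing_p05"
  lab[dn & p < p_moderate] <- "decreasing_p10"
  lab[dn & p < p_high] <- "decreasing_p05"
  factor(lab, levels = trend_class_levels)
}

#' Per-pixel trend classification of annual decay rate maps
#'
#' Runs [mann_kendall()] on each pixel's year-ordered series and maps the
#' results into the five significance classes. Pixels with fewer than
#' `min_n` non-missing years get a missing class.
#'
#' Increasing decay rate trends indicate decreasing vegetation (and are the
#' classes mapped in red in the conventional rendering); `invert = TRUE`
#' recodes the classes as vegetation trends.
#'
#' @param annual_maps A [raster_stack] of annual decay rate layers in year
#'   order (e.g. from [rdk_annual_map()]).
#' @param min_n Minimum valid years per pixel (default 10 of a typical 15).
#' @inheritParams mann_kendall
#' @inheritParams classify_trend
#' @param invert Recode classes as vegetation trends (swap
#'   increasing/decreasing).
#' @return A list: `classes` (single-layer [raster_stack] of integer codes
#'   1..5 matching [trend_class_levels], `NA` for unclassed pixels),
#'   `counts` (tibble of class pixel counts), `p_value` and `s`
#'   (single-layer stacks of the per-pixel test results).
#' @export
trend_map <- function(annual_maps, min_n = 10, continuity = TRUE,
                      tie_correction = TRUE, p_high = 0.05,
                      p_moderate = 0.1, invert = FALSE) {
  stopifnot(inherits(annual_maps, "raster_stack"))
  d <- dim(annual_maps$values)
  if (d[3] < min_n) {
    abort(sprintf("Only %d annual layers; min_n = %d cannot be met anywhere.",
                  d[3], min_n),
          class = "thermdecay_data_error")
  }
  flat <- matrix(annual_maps$values, d[1] * d[2], d[3])
  res <- apply(flat, 1, function(v) {
    mk <- mann_kendall(v, min_n = min_n, continuity = continuity,
                       tie_correction = tie_correction)
    c(mk$s, mk$p_value)
  })
  s <- res[1, ]
  p <- res[2, ]
  cls <- classify_trend(s, p, p_high = p_high, p_moderate = p_moderate)
  if (invert) {
    cls <- factor(trend_class_levels[6 - as.integer(cls)],
                  levels = trend_class_levels)
  }
  g <- annual_maps$grid
  counts <- tibble::tibble(class = factor(trend_class_levels,
                                          levels = trend_class_levels)) |>
    dplyr::left_join(
      tibble::tibble(class = cls) |>
        dplyr::filter(!is.na(.data$class)) |>
        dplyr::count(.data$class),
      by = "class") |>
    tidyr::replace_na(list(n = 0L))
  list(
    classes = raster_stack(matrix(as.integer(cls), g$n_rows, g$n_cols),
                           g, "trend_class", variable_name = "trend_class",
                           units = "code 1-5"),
    counts = counts,
    s = raster_stack(matrix(s, g$n_rows, g$n_cols), g, "s",
                     variable_name = "mk_s", units = "pairs"),
    p_value = raster_stack(matrix(p, g$n_rows, g$n_cols), g, "p",
                           variable_name = "mk_p", units = "probability")
  )
}

#' Reduced major axis regression
#'
#' Symmetric (geometric-mean) regression for comparing two error-bearing
#' measurements, e.g. decay rate maps from two platforms: the slope is
#' `sign(r) * sd(y) / sd(x)` and the intercept `mean(y) - slope * mean(x)`.
#' Unlike ordinary least squares, swapping the axes inverts the slope
#' exactly.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the two measurements.
#' @return An object of class `rma_fit` with `slope`, `intercept`,
#'   `pearson_r`, `n`, and the fitted data for plotting. [tidy()] gives the
#'   coefficients, [glance()] the fit summary.
#' @examples
#' d <- tibble::tibble(a = rnorm(50), b = 2 * rnorm(50))
#' fit <- rma_regression(d, a, b)
#' tidy(fit)
#' @export
rma_regression <- function(data, x, y) {
  stopifnot(is.data.frame(data))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) {
    abort("RMA needs at least 3 complete pairs.",
          class = "thermdecay_data_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("RMA is undefined when either variable has zero variance.",
          class = "thermdecay_data_error")
  }
  r <- cor(xv, yv)
  slope <- sign(r) * sd(yv) / sd(xv)
  if (slope == 0) slope <- sd(yv) / sd(xv)  # r exactly 0: keep magnitude
  structure(
    list(slope = slope, intercept = mean(yv) - slope * mean(xv),
         pearson_r = r, n = length(xv),
         x_name = as_name(enquo(x)), y_name = as_name(enquo(y)),
         data = tibble::tibble(x = xv, y = yv)),
    class = "rma_fit"
  )
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("RMA regression: %s = %.6g * %s + %.6g  (r = %.4f, n = %d)\n",
              x$y_name, x$slope, x$x_name, x$intercept, x$pearson_r, x$n))
  invisible(x)
}

#' @rdname rma_regression
#' @param ... Unused.
#' @export
tidy.rma_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname rma_regression
#' @export
glance.rma_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, n = x$n)
}

#' Pairwise Pearson and Spearman correlation table
#'
#' Cross-correlates a set of co-registered variables over their jointly
#' valid pixels, pairwise-complete (each pair of variables uses every pixel
#' where both are valid, so variables spanning different periods or masks
#' still correlate over their common support). Latitude, when included as a
#' comparison variable, conventionally enters as its absolute value; pass it
#' through `absolute`.
#'
#' @param data A data frame with one row per pixel and one column per
#'   variable (e.g. from [as_tibble.raster_stack()] joins), or a named list
#'   of equal-dimension matrices.
#' @param ... Optional tidy-selection of the variable columns (default: all
#'   numeric columns).
#' @param absolute Character vector of variables to replace by their
#'   absolute value before correlating (e.g. `"latitude"`).
#' @param min_n Minimum jointly valid pixels for an entry (default 3);
#'   pairs below it get `NA`.
#' @return An object of class `correlation_table`: `pearson` and `spearman`
#'   correlation matrices (symmetric, unit diagonal), `n` (pairwise counts)
#'   and `variable_names`. [tidy()] gives a long tibble.
#' @examples
#' d <- tibble::tibble(a = rnorm(30), b = rnorm(30))
#' correlation_table(d)
#' @export
correlation_table <- function(data, ..., absolute = NULL, min_n = 3) {
  if (is.list(data) && !is.data.frame(data) &&
      all(vapply(data, is.matrix, logical(1)))) {
    data <- tibble::as_tibble(lapply(data, as.vector))
  }
  stopifnot(is.data.frame(data))
  sel <- rlang::enquos(...)
  vars <- if (length(sel) > 0) {
    dplyr::select(data, !!!sel)
  } else {
    tibble::as_tibble(data)[vapply(data, is.numeric, logical(1))]
  }
  if (ncol(vars) < 2) {
    abort("At least two variables are required.",
          class = "thermdecay_data_error")
  }
  for (v in intersect(absolute, names(vars))) vars[[v]] <- abs(vars[[v]])

  m <- as.matrix(vars)
  n_mat <- crossprod(!is.na(m))
  pear <- suppressWarnings(cor(m, use = "pairwise.complete.obs",
                               method = "pearson"))
  spear <- suppressWarnings(cor(m, use = "pairwise.complete.obs",
                                method = "spearman"))
  low <- n_mat < min_n
  pear[low] <- NA_real_
  spear[low] <- NA_real_
  diag(pear) <- 1
  diag(spear) <- 1
  structure(list(pearson = pear, spearman = spear, n = n_mat,
                 variable_names = colnames(m)),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("<correlation_table> %d variables\n",
              length(x$variable_names)))
  cat("Pearson:\n")
  print(round(x$pearson, 3))
  cat("Spearman:\n")
  print(round(x$spearman, 3))
  invisible(x)
}

#' @rdname correlation_table
#' @param x A `correlation_table`.
#' @export
tidy.correlation_table <- function(x, ...) {
  vn <- x$variable_names
  tidyr::expand_grid(var1 = vn, var2 = vn) |>
    dplyr::mutate(
      pearson = as.vector(t(x$pearson)),
      spearman = as.vector(t(x$spearman)),
      n = as.vector(t(x$n))
    )
}

#' Write a correlation table to CSV files
#'
#' Writes the Pearson and Spearman matrices as `variables x variables` CSV
#' files plus a combined long-format file.
#'
#' @param ct A [correlation_table()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"correlation"`).
#' @return Paths of the written files, invisibly.
#' @export
write_correlation_csv <- function(ct, dir, prefix = "correlation") {
  stopifnot(inherits(ct, "correlation_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_pearson.csv", "_spearman.csv",
                                           "_long.csv")))
  write.csv(as.data.frame(ct$pearson), paths[1])
  write.csv(as.data.frame(ct$spearman), paths[2])
  write.csv(tidy.correlation_table(ct), paths[3], row.names = FALSE)
  invisible(paths)
}
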