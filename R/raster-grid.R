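#' Grid specification
#'
#' Georeferencing of a regular raster grid: pixel counts, lower-left corner,
#' square cell size, optional CRS label, and the nodata sentinel used in
#' files. Pixel registration is pixel-center, rows are stored top-to-bottom
#' (row 1 is the northernmost), columns left-to-right.
#'
#' @param n_rows,n_cols Pixel counts (positive integers).
#' @param xll,yll Coordinates of the outer corner of the lower-left pixel.
#' @param cellsize Square pixel size in CRS units (positive).
#' @param crs_label Free-text coordinate reference identifier.
#' @param nodata Sentinel written for missing pixels in files (in memory,
#'   missing is always `NA`).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_rows, n_cols, xll = 0, yll = 0, cellsize = 1,
                      crs_label = NA_character_, nodata = -9999) {
  if (n_rows < 1 || n_cols < 1 || cellsize <= 0) {
    abort("Grid needs positive dimensions and cell size.",
          class = "thermdecay_config_error")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 xll = xll, yll = yll, cellsize = cellsize,
                 crs_label = crs_label, nodata = nodata),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols, cell %g, origin (%g, %g)%s\n",
              x$n_rows, x$n_cols, x$cellsize, x$xll, x$yll,
              ifelse(is.na(x$crs_label), "", paste0(", crs ", x$crs_label))))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%g(%g,%g)", x$n_rows, x$n_cols, x$cellsize, x$xll, x$yll)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "xll", "yll", "cellsize")],
                   b[c("n_rows", "n_cols", "xll", "yll", "cellsize")]))
}

# Pixel-center coordinates (row 1 = top).
grid_x <- function(grid) grid$xll + (seq_len(grid$n_cols) - 0.5) * grid$cellsize
grid_y <- function(grid) {
  grid$yll + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cellsize
}

#' Raster stack
#'
#' A set of co-registered raster layers sharing one [grid_spec()]: a 3-D
#' array `n_rows x n_cols x n_layers` (a single matrix is promoted to one
#' layer) with ordered time labels. Missing pixels are `NA`.
#'
#' @param values Numeric matrix or 3-D array of values.
#' @param grid A [grid_spec()] matching the first two dimensions.
#' @param time_labels Character vector of ordered period labels, one per
#'   layer.
#' @param variable_name,units Free-text metadata.
#' @return A `raster_stack` object.
#' @export
raster_stack <- function(values, grid, time_labels = NULL,
                         variable_name = "value", units = "") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3)
  if (dim(values)[1] != grid$n_rows || dim(values)[2] != grid$n_cols) {
    abort("`values` dimensions do not match the grid.",
          class = "thermdecay_data_error")
  }
  n_layers <- dim(values)[3]
  if (is.null(time_labels)) time_labels <- sprintf("layer_%03d", seq_len(n_layers))
  if (length(time_labels) != n_layers) {
    abort("One time label per layer is required.",
          class = "thermdecay_data_error")
  }
  if (is.unsorted(time_labels)) {
    ord <- order(time_labels)
    values <- values[, , ord, drop = FALSE]
    time_labels <- time_labels[ord]
  }
  structure(list(values = values, grid = grid,
                 time_labels = as.character(time_labels),
                 variable_name = variable_name, units = units),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_stack> %s [%s]: %d x %d pixels, %d layer(s)\n",
              x$variable_name, x$units, d[1], d[2], d[3]))
  cat(sprintf("  grid %s; %.1f%% valid\n", format(x$grid),
              100 * mean(!is.na(x$values))))
  if (d[3] > 1) {
    cat("  layers:", paste(head(x$time_labels, 3), collapse = ", "),
        if (d[3] > 3) sprintf("... %s", tail(x$time_labels, 1)) else "", "\n")
  }
  invisible(x)
}

#' @export
dim.raster_stack <- function(x) dim(x$values)

#' Extract one layer of a stack as a matrix
#' @param x A [raster_stack].
#' @param i Layer index or time label.
#' @return The layer as a plain matrix.
#' @export
stack_layer <- function(x, i = 1) {
  stopifnot(inherits(x, "raster_stack"))
  if (is.character(i)) i <- match(i, x$time_labels)
  m <- x$values[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Tidy view of a raster stack
#'
#' @param x A [raster_stack].
#' @param ... Unused.
#' @return A tibble with one row per pixel per layer: `row`, `col`, `x`,
#'   `y` (pixel-center coordinates), `time`, `value`.
#' @export
as_tibble.raster_stack <- function(x, ...) {
  d <- dim(x$values)
  idx <- tidyr::expand_grid(layer = seq_len(d[3]), col = seq_len(d[2]),
                            row = seq_len(d[1]))
  xs <- grid_x(x$grid)[idx$col]
  ys <- grid_y(x$grid)[idx$row]
  times <- x$time_labels[idx$layer]
  vals <- as.vector(x$values)
  tibble::tibble(row = idx$row, col = idx$col, x = xs, y = ys,
                 time = times, value = vals)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster format carrying the full georeferencing
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`). Values are printed with 17 significant digits so a
#' write/read round trip is lossless for doubles. A CRS label, when present,
#' goes to a `.prj` sidecar file.
#'
#' @param x A matrix, or a [raster_stack] (whose layer `layer` is written).
#' @param path Output file path (conventionally `.asc`).
#' @param grid A [grid_spec()]; required when `x` is a bare matrix.
#' @param layer Layer index when `x` is a stack.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, grid = NULL, layer = 1) {
  if (inherits(x, "raster_stack")) {
    grid <- x$grid
    x <- stack_layer(x, layer)
  }
  if (is.null(grid)) {
    abort("A `grid` is required when writing a bare matrix.",
          class = "thermdecay_config_error")
  }
  stopifnot(is.matrix(x), all(dim(x) == c(grid$n_rows, grid$n_cols)))
  vals <- x
  vals[is.na(vals)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", grid$nodata)
  )
  body <- apply(vals, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " "))
  writeLines(c(header, body), path)
  if (!is.na(grid$crs_label)) {
    writeLines(grid$crs_label, paste0(tools::file_path_sans_ext(path), ".prj"))
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_ascii_grid()] or any
#'   conforming tool. A `.prj` sidecar, if present, supplies the CRS label.
#' @param check_kelvin Refuse files whose valid values fall below 150, which
#'   indicates Celsius or unscaled integer input (default `FALSE`; enabled
#'   by the temperature ingest paths).
#' @param scale,offset Applied as `value * scale + offset` after reading,
#'   for sensor products stored as scaled integers.
#' @return A single-layer [raster_stack].
#' @export
read_ascii_grid <- function(path, check_kelvin = FALSE, scale = 1,
                            offset = 0) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "thermdecay_config_error")
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("Malformed ASCII grid header in %s", path),
          class = "thermdecay_data_error")
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    abort(sprintf("Value count mismatch in %s", path),
          class = "thermdecay_data_error")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  m <- m * scale + offset
  if (check_kelvin && any(m < 150, na.rm = TRUE)) {
    abort(sprintf(
      paste0("Values below 150 K in %s: input may be Celsius or scaled ",
             "integers; pass `scale`/`offset` to convert."), path),
      class = "thermdecay_data_error")
  }
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) readLines(prj)[1] else NA_character_
  grid <- grid_spec(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                    hdr$cellsize, crs_label = crs, nodata = nodata)
  raster_stack(m, grid, time_labels = basename(path))
}

#' Read a set of ASCII grids into a stack
#'
#' @param paths Files to read; all must share one grid.
#' @param time_labels Period labels, one per file (default: file names).
#' @inheritParams read_ascii_grid
#' @param variable_name,units Metadata for the stack.
#' @return A [raster_stack] with one layer per file, ordered by label.
#' @export
read_stack <- function(paths, time_labels = NULL, check_kelvin = FALSE,
                       scale = 1, offset = 0, variable_name = "value",
                       units = "") {
  layers <- lapply(paths, read_ascii_grid, check_kelvin = check_kelvin,
                   scale = scale, offset = offset)
  grid <- layers[[1]]$grid
  for (l in layers[-1]) {
    if (!grids_identical(l$grid, grid)) {
      abort("All files in a stack must share one grid.",
            class = "thermdecay_data_error")
    }
  }
  if (is.null(time_labels)) time_labels <- basename(paths)
  arr <- array(NA_real_, c(grid$n_rows, grid$n_cols, length(layers)))
  for (j in seq_along(layers)) arr[, , j] <- stack_layer(layers[[j]])
  raster_stack(arr, grid, time_labels, variable_name, units)
}

#' Regrid a raster stack onto a target grid
#'
#' Downscaling (coarse to fine) assigns each target pixel the value of the
#' source pixel containing its center (nearest neighbor); upscaling (fine to
#' coarse) assigns each target pixel the mean of the valid source pixels
#' whose centers fall inside it, with nodata excluded from the mean and
#' propagated (a cell with no valid contributor is nodata, never 0).
#'
#' @param source A [raster_stack].
#' @param target A [grid_spec()] in the same coordinate system.
#' @param method `"auto"` picks nearest-neighbor when the target cell is
#'   finer than the source and block-mean when coarser; `"nearest"` or
#'   `"mean"` force a direction.
#' @return A [raster_stack] on `target`.
#' @export
regrid <- function(source, target, method = c("auto", "nearest", "mean")) {
  stopifnot(inherits(source, "raster_stack"), inherits(target, "grid_spec"))
  method <- match.arg(method)
  sg <- source$grid
  sx <- c(sg$xll, sg$xll + sg$n_cols * sg$cellsize)
  sy <- c(sg$yll, sg$yll + sg$n_rows * sg$cellsize)
  tx <- c(target$xll, target$xll + target$n_cols * target$cellsize)
  ty <- c(target$yll, target$yll + target$n_rows * target$cellsize)
  if (tx[1] >= sx[2] || tx[2] <= sx[1] || ty[1] >= sy[2] || ty[2] <= sy[1]) {
    abort("Source and target extents do not overlap.",
          class = "thermdecay_data_error")
  }
  if (method == "auto") {
    method <- if (target$cellsize > sg$cellsize) "mean" else "nearest"
  }

  d <- dim(source$values)
  out <- array(NA_real_, c(target$n_rows, target$n_cols, d[3]))

  if (method == "nearest") {
    # Source pixel containing each target pixel center.
    col_of <- floor((grid_x(target) - sg$xll) / sg$cellsize) + 1
    row_of <- floor((sy[2] - grid_y(target)) / sg$cellsize) + 1
    col_of[col_of < 1 | col_of > sg$n_cols] <- NA
    row_of[row_of < 1 | row_of > sg$n_rows] <- NA
    ri <- rep(row_of, times = target$n_cols)
    ci <- rep(col_of, each = target$n_rows)
    flat <- (ci - 1) * sg$n_rows + ri
    for (j in seq_len(d[3])) {
      layer <- source$values[, , j]
      out[, , j] <- matrix(layer[flat], target$n_rows, target$n_cols)
    }
  } else {
    # Target cell containing each source pixel center.
    tc <- floor((grid_x(sg) - target$xll) / target$cellsize) + 1
    tr <- floor((ty[2] - grid_y(sg)) / target$cellsize) + 1
    tc[tc < 1 | tc > target$n_cols] <- NA
    tr[tr < 1 | tr > target$n_rows] <- NA
    ri <- rep(tr, times = sg$n_cols)
    ci <- rep(tc, each = sg$n_rows)
    dest <- (ci - 1) * target$n_rows + ri
    keep <- !is.na(dest)
    n_cells <- target$n_rows * target$n_cols
    for (j in seq_len(d[3])) {
      v <- as.vector(source$values[, , j])
      ok <- keep & !is.na(v)
      sums <- rep(0, n_cells)
      cnts <- rep(0, n_cells)
      if (any(ok)) {
        agg_s <- tapply(v[ok], dest[ok], sum)
        agg_n <- tapply(v[ok], dest[ok], length)
        ids <- as.integer(names(agg_s))
        sums[ids] <- agg_s
        cnts[ids] <- agg_n
      }
      res <- ifelse(cnts > 0, sums / cnts, NA_real_)
      out[, , j] <- matrix(res, target$n_rows, target$n_cols)
    }
  }
  raster_stack(out, target, source$time_labels, source$variable_name,
               source$units)
}

#' Mask a stack by a thresholded ancillary raster
#'
#' Sets pixels failing a threshold predicate on an ancillary single-band
#' raster (e.g. long-term mean annual precipitation) to missing in every
#' layer of the stack. The conventional aridity mask keeps pixels with MAP
#' strictly greater than 100 mm/yr.
#'
#' @param stack A [raster_stack] to mask.
#' @param mask_raster A single-layer [raster_stack] on the same grid (regrid
#'   it first if needed).
#' @param threshold Threshold value (default 100).
#' @param keep `"above"` keeps pixels with mask `> threshold` (strict;
#'   default), `"below"` keeps `< threshold`.
#' @return The masked [raster_stack], with attribute `n_retained` (count of
#'   pixels passing the predicate).
#' @export
mask_by_threshold <- function(stack, mask_raster, threshold = 100,
                              keep = c("above", "below")) {
  stopifnot(inherits(stack, "raster_stack"),
            inherits(mask_raster, "raster_stack"))
  keep <- match.arg(keep)
  if (!grids_identical(stack$grid, mask_raster$grid)) {
    abort("Mask grid does not match the stack grid; regrid it first.",
          class = "thermdecay_data_error")
  }
  m <- stack_layer(mask_raster, 1)
  pass <- if (keep == "above") m > threshold else m < threshold
  pass[is.na(pass)] <- FALSE
  for (j in seq_len(dim(stack$values)[3])) {
    layer <- stack$values[, , j]
    layer[!pass] <- NA_real_
    stack$values[, , j] <- layer
  }
  attr(stack, "n_retained") <- sum(pass)
  stack
}

#' Per-pixel annual mean decay rate maps
#'
#' Applies the per-pair decay rate estimator to aligned day and night
#' temperature stacks and averages within year groups, pixel by pixel. A
#' pixel-date pair is valid only when both the day and the night value are
#' present. Produces a decay rate layer and a companion valid-pair-count
#' layer per year.
#'
#' @param day_stack,night_stack [raster_stack]s aligned in grid and time
#'   (identical time labels, Kelvin values).
#' @param delta_t Hours between the day and night acquisitions (default 12).
#' @param year_of Function mapping a time label to its year group label;
#'   the default takes the first 4 characters (labels like `"2005-121"`).
#' @param min_pairs Minimum valid pairs per pixel-year (default 10); below
#'   it the rate is `NA` but the count layer still records the pairs seen.
#' @param mask_warm_nights Exclude pairs with `t_night > t_day` from the
#'   mean.
#' @return A list: `rdk` ([raster_stack], one layer per year, 1/hr),
#'   `n_pairs` (matching count stack), `warm_night_frac` (scalar fraction of
#'   valid pairs that were warm-night).
#' @export
rdk_annual_map <- function(day_stack, night_stack, delta_t = 12,
                           year_of = function(l) substr(l, 1, 4),
                           min_pairs = 10, mask_warm_nights = FALSE) {
  stopifnot(inherits(day_stack, "raster_stack"),
            inherits(night_stack, "raster_stack"))
  if (!grids_identical(day_stack$grid, night_stack$grid) ||
      !identical(day_stack$time_labels, night_stack$time_labels)) {
    abort("Day and night stacks must be aligned in grid and time.",
          class = "thermdecay_data_error")
  }
  years <- year_of(day_stack$time_labels)
  uy <- sort(unique(years))
  g <- day_stack$grid
  d <- dim(day_stack$values)

  # Per-layer per-pixel rate; invalid (either side missing) stays NA.
  td <- day_stack$values
  tn <- night_stack$values
  ok <- !is.na(td) & !is.na(tn)
  if (any(td[ok] <= 0) || any(tn[ok] <= 0)) {
    abort("Non-positive temperatures: stacks must be in Kelvin.",
          class = "thermdecay_data_error")
  }
  if (any(td[ok] < 150) || any(tn[ok] < 150)) {
    abort(paste0("Temperatures below 150 K: input may be Celsius or scaled ",
                 "integers; apply `scale`/`offset` at read time."),
          class = "thermdecay_data_error")
  }
  rates <- array(NA_real_, d)
  rates[ok] <- log(td[ok] / tn[ok]) / delta_t
  warm <- ok & (tn > td)
  if (mask_warm_nights) rates[warm] <- NA_real_

  rdk_arr <- array(NA_real_, c(g$n_rows, g$n_cols, length(uy)))
  np_arr <- array(NA_real_, c(g$n_rows, g$n_cols, length(uy)))
  for (yi in seq_along(uy)) {
    sel <- which(years == uy[yi])
    sub <- rates[, , sel, drop = FALSE]
    np <- apply(!is.na(sub), c(1, 2), sum)
    mu <- apply(sub, c(1, 2), function(v) {
      nv <- sum(!is.na(v))
      if (nv >= min_pairs) mean(v, na.rm = TRUE) else NA_real_
    })
    rdk_arr[, , yi] <- mu
    np_arr[, , yi] <- np
  }
  list(
    rdk = raster_stack(rdk_arr, g, uy, variable_name = "rdk", units = "1/hr"),
    n_pairs = raster_stack(np_arr, g, uy, variable_name = "n_pairs",
                           units = "count"),
    warm_night_frac = if (any(ok)) sum(warm) / sum(ok) else NA_real_
  )
}
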