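#' Diurnal land surface temperature model
#'
#' A minimal two-branch diurnal cycle: a half-sinusoid heating branch from
#' dawn to the afternoon temperature peak, then Newtonian exponential
#' cooling toward the ambient temperature until the next dawn. The cooling
#' branch is the physics the decay rate index inverts; the heating branch is
#' deliberately simple plumbing — any continuous curve peaking in the early
#' afternoon reproduces the day/night sampling geometry of polar-orbiting
#' platforms.
#'
#' Fields may be vectors or matrices (recycled against each other), so one
#' model object can describe a whole scene with spatially varying `k`.
#'
#' @param k True cooling constant, 1/hr. Positive.
#' @param t_ambient Nighttime ambient temperature, Kelvin (default 285).
#' @param t_peak Diurnal maximum temperature, Kelvin (default 310). Must
#'   exceed `t_ambient`.
#' @param peak_hour Local solar hour of the diurnal maximum (default 13.5).
#' @param dawn_hour Local hour at which heating starts (default 6).
#' @param heating A function `(frac) -> [0, 1]` mapping the normalized
#'   dawn-to-peak time fraction onto the normalized temperature rise;
#'   default is the half-sinusoid `sin(pi/2 * frac)`.
#' @return An object of class `diurnal_model`.
#' @examples
#' m <- diurnal_model(k = 0.05)
#' diurnal_temperature(m, hour = c(1.5, 10.5, 13.5, 22.5))
#' @export
diurnal_model <- function(k, t_ambient = 285, t_peak = 310,
                          peak_hour = 13.5, dawn_hour = 6,
                          heating = function(frac) sin(pi / 2 * frac)) {
  if (any(k <= 0)) {
    abort("`k` must be positive.", class = "thermdecay_domain_error")
  }
  if (any(t_peak <= t_ambient)) {
    abort("`t_peak` must exceed `t_ambient`.",
          class = "thermdecay_domain_error")
  }
  if (peak_hour < 0 || peak_hour >= 24 || dawn_hour < 0 || dawn_hour >= 24 ||
      dawn_hour >= peak_hour) {
    abort("Hours must lie in [0, 24) with dawn before the peak.",
          class = "thermdecay_domain_error")
  }
  structure(
    list(k = k, t_ambient = t_ambient, t_peak = t_peak,
         peak_hour = peak_hour, dawn_hour = dawn_hour, heating = heating),
    class = "diurnal_model"
  )
}

#' @export
print.diurnal_model <- function(x, ...) {
  cat("<diurnal_model>\n")
  cat(sprintf("  k:         %s 1/hr\n",
              paste(format(range(x$k)), collapse = " .. ")))
  cat(sprintf("  t_ambient: %s K, t_peak: %s K\n",
              paste(format(range(x$t_ambient)), collapse = " .. "),
              paste(format(range(x$t_peak)), collapse = " .. ")))
  cat(sprintf("  peak %.1f h, dawn %.1f h\n", x$peak_hour, x$dawn_hour))
  invisible(x)
}

#' Evaluate the diurnal temperature cycle at a local hour
#'
#' Post-peak hours (including the pre-dawn hours of the next calendar day)
#' follow [exact_cooling()] started at the peak; dawn-to-peak hours follow
#' the heating branch rising from the pre-dawn cooling endpoint to the peak.
#' The curve is continuous at dawn and at the peak.
#'
#' @param model A [diurnal_model()].
#' @param hour Local solar hour in `[0, 24)`. Either a scalar (evaluated for
#'   every model pixel) or a vector matched against scalar model fields.
#' @return Temperature(s), Kelvin, with the shape of the broadcast inputs.
#' @export
diurnal_temperature <- function(model, hour) {
  stopifnot(inherits(model, "diurnal_model"))
  if (any(hour < 0 | hour >= 24)) {
    abort("`hour` must lie in [0, 24).", class = "thermdecay_domain_error")
  }
  k <- model$k
  ta <- model$t_ambient
  tp <- model$t_peak
  ph <- model$peak_hour
  dh <- model$dawn_hour

  # Hours since the governing peak: hours after ph cool from today's peak,
  # hours before dawn cool from yesterday's.
  elapsed_cool <- ifelse(hour >= ph, hour - ph, hour + 24 - ph)
  cooled <- ta + (tp - ta) * exp(-k * elapsed_cool)

  # Heating branch: rise from the pre-dawn cooling endpoint to the peak.
  t_dawn <- ta + (tp - ta) * exp(-k * (dh + 24 - ph))
  frac <- pmin(pmax((hour - dh) / (ph - dh), 0), 1)
  heated <- t_dawn + (tp - t_dawn) * model$heating(frac)

  if (length(hour) == 1) {
    # Scalar hour with possibly gridded model fields: keep the field shape.
    if (hour >= dh && hour < ph) heated else cooled
  } else {
    in_heating <- hour >= dh & hour < ph
    ifelse(in_heating, heated, cooled)
  }
}

#' Satellite overpass schedule
#'
#' Local acquisition hours of the day and night observations. Presets match
#' the near-equator overpass times of the two MODIS platforms: Aqua at
#' ~13:30 / ~01:30 and Terra at ~10:30 / ~22:30 local solar time.
#'
#' @param platform `"aqua"` or `"terra"`, or `NULL` when giving explicit
#'   hours.
#' @param day_hour,night_hour Explicit local hours in `[0, 24)`; override
#'   the platform preset.
#' @return An `overpass_schedule` object with `day_hour`, `night_hour`,
#'   `platform_label` and the implied `delta_t` (hours from day to the next
#'   night acquisition).
#' @examples
#' overpass_schedule("aqua")
#' overpass_schedule(day_hour = 11, night_hour = 23)
#' @export
overpass_schedule <- function(platform = NULL, day_hour = NULL,
                              night_hour = NULL) {
  if (!is.null(platform)) {
    platform <- match.arg(tolower(platform), c("aqua", "terra"))
    preset <- switch(platform,
                     aqua = c(13.5, 1.5),
                     terra = c(10.5, 22.5))
    if (is.null(day_hour)) day_hour <- preset[1]
    if (is.null(night_hour)) night_hour <- preset[2]
    label <- platform
  } else {
    label <- "custom"
  }
  if (is.null(day_hour) || is.null(night_hour)) {
    abort("Give a `platform` preset or both `day_hour` and `night_hour`.",
          class = "thermdecay_config_error")
  }
  if (day_hour < 0 || day_hour >= 24 || night_hour < 0 || night_hour >= 24) {
    abort("Overpass hours must lie in [0, 24).",
          class = "thermdecay_config_error")
  }
  delta_t <- (night_hour - day_hour) %% 24
  structure(list(day_hour = day_hour, night_hour = night_hour,
                 platform_label = label, delta_t = delta_t),
            class = "overpass_schedule")
}

#' @export
print.overpass_schedule <- function(x, ...) {
  cat(sprintf("<overpass_schedule> %s: day %.1f h, night %.1f h (dt = %.1f h)\n",
              x$platform_label, x$day_hour, x$night_hour, x$delta_t))
  invisible(x)
}

#' Sample a diurnal model at satellite overpass times
#'
#' Evaluates the diurnal cycle at the schedule's day and night hours for each
#' acquisition date, optionally adding independent zero-mean Gaussian noise
#' to each temperature (satellite LST error is temperature-domain, so noise
#' is added to the temperatures, never to the derived rates).
#'
#' @param model A [diurnal_model()] with scalar fields (one pixel); for full
#'   scenes use [make_scene()].
#' @param schedule An [overpass_schedule()].
#' @param dates Vector of date labels (one paired observation each).
#' @param noise_sd Gaussian noise standard deviation, K (default 0).
#' @return A tibble with one row per date: `date`, `t_day`, `t_night`,
#'   `delta_t`, `valid`.
#' @examples
#' m <- diurnal_model(k = 0.02)
#' sample_overpass(m, overpass_schedule("aqua"), dates = 1:46)
#' @export
sample_overpass <- function(model, schedule, dates, noise_sd = 0) {
  stopifnot(inherits(schedule, "overpass_schedule"))
  n <- length(dates)
  t_day <- rep_len(diurnal_temperature(model, schedule$day_hour), n)
  t_night <- rep_len(diurnal_temperature(model, schedule$night_hour), n)
  if (noise_sd > 0) {
    t_day <- t_day + rnorm(n, sd = noise_sd)
    t_night <- t_night + rnorm(n, sd = noise_sd)
  }
  tibble::tibble(date = dates, t_day = t_day, t_night = t_night,
                 delta_t = schedule$delta_t, valid = TRUE)
}

# Deterministic smooth spatial field in [0, 1]: a diagonal gradient with a
# gentle sinusoidal undulation, so that truth_k varies smoothly and has no
# ties. Truth is parameter-determined (no RNG) so that changing the seed
# changes only noise and clouds, never the ground truth.
smooth_field01 <- function(n_rows, n_cols) {
  r <- matrix(seq(0, 1, length.out = n_rows), n_rows, n_cols)
  c <- matrix(seq(0, 1, length.out = n_cols), n_rows, n_cols, byrow = TRUE)
  f <- 0.6 * c + 0.25 * r + 0.15 * (0.5 + 0.5 * sin(2 * pi * (c + 0.3 * r)))
  (f - min(f)) / (max(f) - min(f))
}

#' Simulate a multi-year day/night land surface temperature scene
#'
#' Forward simulator for the whole analysis stack: a gridded field of true
#' cooling constants (smooth spatial gradient — dense vegetation cools
#' slowly, sparse vegetation fast), an optional per-year linear trend in the
#' constants, per-date satellite-like day/night sampling, additive Gaussian
#' observation noise, and cloud masking that invalidates the day and night
#' values of a pixel jointly.
#'
#' The true decay field is a deterministic function of the scene parameters;
#' the seed controls only noise and cloud placement. Identical calls with the
#' same seed are bit-identical.
#'
#' @param n_rows,n_cols Scene dimensions in pixels.
#' @param years Integer vector of simulated years (default 2003:2017, the
#'   15-year span typical of a MODIS record).
#' @param n_composites Paired observations per year (default 46, the 8-day
#'   compositing calendar).
#' @param k_range Range of true cooling constants across the scene, 1/hr
#'   (default `c(0.005, 0.03)`).
#' @param t_ambient Nighttime ambient temperature, K (default 285).
#' @param t_peak Diurnal maximum temperature, K (default 310).
#' @param trend_slope Per-year additive change of the true cooling constant,
#'   1/hr/yr. A scalar or an `n_rows` x `n_cols` matrix.
#' @param cloud_fraction Per-date independent probability that a pixel's
#'   day/night pair is invalidated (default 0).
#' @param noise_sd Gaussian temperature noise, K (default 0).
#' @param schedule An [overpass_schedule()] (default Aqua).
#' @param peak_hour,dawn_hour Diurnal cycle geometry, local hours.
#' @param seed Integer seed controlling noise and clouds. Required when
#'   either is active.
#' @return A `sim_scene` object: `truth_k` (matrix, year-1 truth),
#'   `trend_slope` (matrix), `day`/`night` (arrays `n_rows x n_cols x
#'   n_dates`), `valid` (logical array, FALSE where cloud-masked), `dates`
#'   (tibble: layer, year, composite, label), `grid` ([grid_spec()]),
#'   `schedule`, `params`, `seed`.
#' @examples
#' sc <- make_scene(n_rows = 8, n_cols = 8, years = 2003:2005,
#'                  n_composites = 10, seed = 1)
#' sc
#' @export
make_scene <- function(n_rows = 40, n_cols = 40, years = 2003:2017,
                       n_composites = 46, k_range = c(0.005, 0.03),
                       t_ambient = 285, t_peak = 310, trend_slope = 0,
                       cloud_fraction = 0, noise_sd = 0,
                       schedule = overpass_schedule("aqua"),
                       peak_hour = 13.5, dawn_hour = 6, seed = NULL) {
  if (n_rows < 1 || n_cols < 1) {
    abort("Scene must have at least one pixel.",
          class = "thermdecay_config_error")
  }
  if (length(years) < 1 || n_composites < 1) {
    abort("At least one year and one composite per year are required.",
          class = "thermdecay_config_error")
  }
  if (any(k_range <= 0) || k_range[2] < k_range[1]) {
    abort("`k_range` must be positive and ordered.",
          class = "thermdecay_config_error")
  }
  stochastic <- cloud_fraction > 0 || noise_sd > 0
  if (stochastic && is.null(seed)) {
    abort("A `seed` is required when noise or clouds are simulated.",
          class = "thermdecay_config_error")
  }

  truth_k <- k_range[1] + diff(k_range) * smooth_field01(n_rows, n_cols)
  slope <- if (is.matrix(trend_slope)) trend_slope else
    matrix(trend_slope, n_rows, n_cols)
  if (!all(dim(slope) == c(n_rows, n_cols))) {
    abort("`trend_slope` matrix must match the scene dimensions.",
          class = "thermdecay_config_error")
  }

  n_years <- length(years)
  n_dates <- n_years * n_composites
  day <- array(NA_real_, c(n_rows, n_cols, n_dates))
  night <- array(NA_real_, c(n_rows, n_cols, n_dates))
  valid <- array(TRUE, c(n_rows, n_cols, n_dates))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  layer <- 0L
  for (iy in seq_len(n_years)) {
    k_y <- pmax(truth_k + slope * (years[iy] - years[1]), 1e-6)
    model <- diurnal_model(k = k_y, t_ambient = t_ambient, t_peak = t_peak,
                           peak_hour = peak_hour, dawn_hour = dawn_hour)
    td <- diurnal_temperature(model, schedule$day_hour)
    tn <- diurnal_temperature(model, schedule$night_hour)
    for (ic in seq_len(n_composites)) {
      layer <- layer + 1L
      d <- td
      n <- tn
      if (noise_sd > 0) {
        d <- d + matrix(rnorm(n_rows * n_cols, sd = noise_sd), n_rows, n_cols)
        n <- n + matrix(rnorm(n_rows * n_cols, sd = noise_sd), n_rows, n_cols)
      }
      if (cloud_fraction > 0) {
        cl <- matrix(runif(n_rows * n_cols) < cloud_fraction, n_rows, n_cols)
        d[cl] <- NA_real_
        n[cl] <- NA_real_
        valid[, , layer][cl] <- FALSE
      }
      day[, , layer] <- d
      night[, , layer] <- n
    }
  }

  dates <- tidyr::expand_grid(year = years,
                              composite = seq_len(n_composites)) |>
    dplyr::mutate(layer = dplyr::row_number(),
                  label = sprintf("%d-%03d", .data$year,
                                  (.data$composite - 1L) * 8L + 1L)) |>
    dplyr::relocate("layer")

  structure(
    list(truth_k = truth_k, trend_slope = slope, day = day, night = night,
         valid = valid, dates = dates,
         grid = grid_spec(n_rows, n_cols),
         schedule = schedule,
         params = list(years = years, n_composites = n_composites,
                       k_range = k_range, t_ambient = t_ambient,
                       t_peak = t_peak, cloud_fraction = cloud_fraction,
                       noise_sd = noise_sd, peak_hour = peak_hour,
                       dawn_hour = dawn_hour),
         seed = seed),
    class = "sim_scene"
  )
}

#' @export
print.sim_scene <- function(x, ...) {
  d <- dim(x$day)
  cat(sprintf("<sim_scene> %d x %d pixels, %d dates (%d years x %d composites)\n",
              d[1], d[2], d[3], length(x$params$years),
              x$params$n_composites))
  cat(sprintf("  truth_k: %.4g .. %.4g 1/hr; platform %s\n",
              min(x$truth_k), max(x$truth_k), x$schedule$platform_label))
  cat(sprintf("  noise_sd %.2g K, cloud_fraction %.2g, seed %s\n",
              x$params$noise_sd, x$params$cloud_fraction,
              ifelse(is.null(x$seed), "none", x$seed)))
  invisible(x)
}

#' Scene observations as a tidy pairs table
#'
#' Flattens a simulated scene into the long table the tabular estimators
#' consume: one row per pixel per date.
#'
#' @param scene A [make_scene()] result.
#' @return A tibble with columns `row`, `col`, `year`, `composite`, `date`,
#'   `t_day`, `t_night`, `delta_t`, `valid`, `truth_k`.
#' @export
scene_pairs <- function(scene) {
  stopifnot(inherits(scene, "sim_scene"))
  d <- dim(scene$day)
  idx <- tidyr::expand_grid(layer = seq_len(d[3]),
                            col = seq_len(d[2]),
                            row = seq_len(d[1]))
  tibble::tibble(
    row = idx$row, col = idx$col,
    layer = idx$layer,
    t_day = as.vector(scene$day),
    t_night = as.vector(scene$night),
    valid = as.vector(scene$valid),
    delta_t = scene$schedule$delta_t,
    truth_k = as.vector(scene$truth_k)[(idx$col - 1L) * d[1] + idx$row]
  ) |>
    dplyr::left_join(scene$dates, by = "layer") |>
    dplyr::rename(date = "label") |>
    dplyr::relocate("row", "col", "year", "composite", "date")
}

#' Day/night raster stacks from a simulated scene
#'
#' @param scene A [make_scene()] result.
#' @return A list with `day` and `night` [raster_stack] objects labelled by
#'   composite date, ready for [rdk_annual_map()].
#' @export
scene_stacks <- function(scene) {
  stopifnot(inherits(scene, "sim_scene"))
  list(
    day = raster_stack(scene$day, scene$grid, scene$dates$label,
                       variable_name = "lst_day", units = "K"),
    night = raster_stack(scene$night, scene$grid, scene$dates$label,
                         variable_name = "lst_night", units = "K")
  )
}
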