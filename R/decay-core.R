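#' Newtonian cooling curve
#'
#' Temperature of a body cooling from an initial temperature `t0` toward a
#' constant ambient temperature `t_ambient` under Newton's law of cooling,
#' `T(t) = T_a + (T_0 - T_a) * exp(-k * t)`.
#'
#' All temperatures are absolute (Kelvin). Arguments are recycled to a common
#' length, so a single call can evaluate a grid of states.
#'
#' @param t Elapsed time since the initial condition, in the inverse units of
#'   `k` (hours when `k` is in 1/hr). Must be non-negative.
#' @param t0 Initial temperature at `t = 0`, Kelvin. Must be positive.
#' @param t_ambient Ambient temperature the body cools toward, Kelvin.
#'   Must be non-negative.
#' @param k Decay constant, in inverse time units. Must be non-negative.
#' @return Numeric vector of temperatures, Kelvin.
#' @examples
#' exact_cooling(t = 12, t0 = 300, t_ambient = 280, k = 0.1)
#' @seealso [rdk_estimate()] for the inverse problem, [approximation_bias()]
#'   for the error incurred by ignoring the ambient term.
#' @export
exact_cooling <- function(t, t0, t_ambient, k) {
  if (any(t < 0, na.rm = TRUE)) {
    abort("`t` must be non-negative: cooling is evaluated forward in time.",
          class = "thermdecay_domain_error")
  }
  if (any(t0 <= 0, na.rm = TRUE)) {
    abort("`t0` must be positive (absolute temperature scale).",
          class = "thermdecay_domain_error")
  }
  if (any(t_ambient < 0, na.rm = TRUE) || any(k < 0, na.rm = TRUE)) {
    abort("`t_ambient` and `k` must be non-negative.",
          class = "thermdecay_domain_error")
  }
  t_ambient + (t0 - t_ambient) * exp(-k * t)
}

#' Per-pair thermal decay rate estimate
#'
#' Estimates the thermal decay rate R_dk from one paired day/night land
#' surface temperature observation as `ln(t_day / t_night) / delta_t`. The
#' estimate inverts Newtonian cooling from the daytime temperature toward
#' the nighttime temperature under the approximation that the ambient
#' temperature is negligible relative to the daytime temperature; see
#' [approximation_bias()] for the bias this incurs when it is not.
#'
#' Temperatures must be on an absolute scale (Kelvin): the day/night *ratio*
#' is what carries the signal, so Celsius input is meaningless. Values below
#' 150 K are rejected as almost certainly not Kelvin.
#'
#' Warm nights (`t_night > t_day`) produce a negative rate. The value is
#' returned, not clamped, and a warning summarising the affected fraction is
#' raised once per call; set `mask_warm_nights = TRUE` to replace them with
#' `NA` instead.
#'
#' @param t_day Daytime land surface temperature, Kelvin.
#' @param t_night Nighttime land surface temperature, Kelvin.
#' @param delta_t Elapsed time between the day and night observations, hours.
#'   Defaults to 12, the separation implied by the Aqua (13:30/01:30) and
#'   Terra (10:30/22:30) local overpass times.
#' @param mask_warm_nights If `TRUE`, pairs with `t_night > t_day` yield `NA`
#'   rather than a negative rate.
#' @param warn_warm_nights Emit a warning when warm-night pairs are present.
#' @return Numeric vector of decay rates in 1/hr (for `delta_t` in hours).
#'   `NA` inputs propagate to `NA`.
#' @examples
#' rdk_estimate(t_day = 300, t_night = 290)          # ~2.8e-3 / hr
#' rdk_estimate(300, 290, delta_t = 12)
#' @export
rdk_estimate <- function(t_day, t_night, delta_t = 12,
                         mask_warm_nights = FALSE, warn_warm_nights = TRUE) {
  n <- max(length(t_day), length(t_night), length(delta_t))
  t_day <- rep_len(t_day, n)
  t_night <- rep_len(t_night, n)
  delta_t <- rep_len(delta_t, n)

  ok <- !is.na(t_day) & !is.na(t_night) & !is.na(delta_t)
  if (any(t_day[ok] <= 0) || any(t_night[ok] <= 0)) {
    abort(paste0("Non-positive temperatures: R_dk needs absolute (Kelvin) ",
                 "temperatures."),
          class = "thermdecay_domain_error")
  }
  if (any(t_day[ok] < 150) || any(t_night[ok] < 150)) {
    abort(paste0("Temperatures below 150 K found; input may be Celsius or ",
                 "unscaled integers. Apply the sensor scale/offset first."),
          class = "thermdecay_domain_error")
  }
  if (any(delta_t[ok] <= 0)) {
    abort("`delta_t` must be positive (hours between day and night).",
          class = "thermdecay_domain_error")
  }

  rdk <- log(t_day / t_night) / delta_t
  warm <- ok & (t_night > t_day)
  if (any(warm)) {
    if (warn_warm_nights) {
      warn(sprintf(
        "%d of %d pairs (%.1f%%) have t_night > t_day (negative R_dk).",
        sum(warm), sum(ok), 100 * sum(warm) / sum(ok)),
        class = "thermdecay_warm_night")
    }
    if (mask_warm_nights) rdk[warm] <- NA_real_
  }
  rdk
}

#' Add per-pair decay rate and diurnal range columns to a pairs table
#'
#' Data-frame-first wrapper around [rdk_estimate()] and [dtr()]: takes a
#' table of paired day/night observations and appends `rdk`, `dtr` and
#' `warm_night` columns. Rows with `valid == FALSE` (when a `valid` column is
#' present) get `NA` in all derived columns.
#'
#' @param pairs Data frame with columns `t_day`, `t_night` (Kelvin), and
#'   optionally `delta_t` (hours) and `valid` (logical).
#' @param delta_t Hours between observations; used when `pairs` has no
#'   `delta_t` column.
#' @inheritParams rdk_estimate
#' @return The input as a tibble with `rdk` (1/hr), `dtr` (K) and
#'   `warm_night` (logical) columns appended.
#' @examples
#' pairs <- tibble::tibble(t_day = c(300, 305), t_night = c(290, 288))
#' rdk_pairs(pairs)
#' @export
rdk_pairs <- function(pairs, delta_t = 12, mask_warm_nights = FALSE,
                      warn_warm_nights = TRUE) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("t_day", "t_night") %in% names(pairs))) {
    abort("`pairs` needs `t_day` and `t_night` columns.",
          class = "thermdecay_config_error")
  }
  pairs <- tibble::as_tibble(pairs)
  dt <- if ("delta_t" %in% names(pairs)) pairs$delta_t else delta_t
  valid <- if ("valid" %in% names(pairs)) pairs$valid else TRUE
  valid <- rep_len(valid, nrow(pairs)) & !is.na(pairs$t_day) &
    !is.na(pairs$t_night)

  td <- ifelse(valid, pairs$t_day, NA_real_)
  tn <- ifelse(valid, pairs$t_night, NA_real_)
  pairs$rdk <- rdk_estimate(td, tn, dt, mask_warm_nights = mask_warm_nights,
                            warn_warm_nights = warn_warm_nights)
  pairs$dtr <- dtr(td, tn)
  pairs$warm_night <- valid & (pairs$t_night > pairs$t_day)
  pairs
}

#' Diurnal temperature range of a day/night pair
#'
#' The day-minus-night land surface temperature difference, in Kelvin. A
#' simpler companion statistic to the decay rate; its annual aggregation in
#' [rdk_annual()] follows the same valid-pair averaging as R_dk.
#'
#' @inheritParams rdk_estimate
#' @return Numeric vector, `t_day - t_night` in K; `NA` propagates.
#' @examples
#' dtr(300, 290)
#' @export
dtr <- function(t_day, t_night) {
  t_day - t_night
}

#' Annual (or per-period) mean thermal decay rate
#'
#' Aggregates per-pair decay rate estimates into the annual mean index
#' R-bar_dk: the arithmetic mean of `ln(t_day/t_night)/delta_t` over the
#' valid pairs of each period. Cloudy/missing pairs (`valid == FALSE` or
#' `NA` temperatures) are excluded; periods with fewer than `min_pairs`
#' valid pairs yield `NA` with the pair count still recorded.
#'
#' @param pairs Data frame of paired observations: columns `t_day`,
#'   `t_night`, optional `delta_t`, `valid`, plus any grouping columns.
#' @param ... Grouping columns identifying the aggregation period
#'   (e.g. `year`), passed unquoted. If omitted, existing `dplyr` groups are
#'   used; with neither, the whole table is one period.
#' @param delta_t Hours between day and night observations when `pairs`
#'   lacks a `delta_t` column.
#' @param min_pairs Minimum number of valid pairs for a non-missing mean.
#'   Default 10 (8-day composites give at most 46 pairs per year).
#' @param mask_warm_nights Exclude warm-night (negative-rate) pairs from the
#'   mean instead of including their negative values.
#' @return A tibble with one row per period: grouping columns, `rdk` (mean
#'   decay rate, 1/hr), `dtr` (mean diurnal range, K), `n_pairs` (valid
#'   pairs used) and `warm_night_frac` (fraction of valid pairs with
#'   `t_night > t_day`).
#' @examples
#' pairs <- tibble::tibble(
#'   year = rep(c(2003, 2004), each = 12),
#'   t_day = 300 + rnorm(24), t_night = 290 + rnorm(24)
#' )
#' rdk_annual(pairs, year)
#' @export
rdk_annual <- function(pairs, ..., delta_t = 12, min_pairs = 10,
                       mask_warm_nights = FALSE) {
  pairs <- rdk_pairs(pairs, delta_t = delta_t,
                     mask_warm_nights = mask_warm_nights,
                     warn_warm_nights = FALSE)
  grp <- rlang::enquos(...)
  if (length(grp) > 0) pairs <- dplyr::group_by(pairs, !!!grp)

  dplyr::summarise(
    pairs,
    n_pairs = sum(!is.na(.data$rdk)),
    n_considered = sum(!is.na(.data$rdk) | .data$warm_night),
    warm_night_frac = ifelse(n_considered > 0,
                             sum(.data$warm_night, na.rm = TRUE) /
                               n_considered,
                             NA_real_),
    rdk = ifelse(n_pairs >= min_pairs,
                 mean(.data$rdk, na.rm = TRUE), NA_real_),
    dtr = ifelse(n_pairs >= min_pairs,
                 mean(.data$dtr, na.rm = TRUE), NA_real_),
    .groups = "drop"
  ) |>
    dplyr::select(-"n_considered") |>
    dplyr::relocate(dplyr::any_of(c("rdk", "dtr", "n_pairs",
                                    "warm_night_frac")),
                    .after = dplyr::last_col())
}

#' Theoretical decay rate from thermal properties
#'
#' The decay constant implied by the physical properties of the cooling
#' body: `alpha_tot / (rho * c * (V/A))`. Dense vegetation — high density,
#' high specific heat, high volume-to-surface-area ratio (large thermal
#' mass) — cools slowly and has a small decay rate; sparse vegetation and
#' bare soil cool fast.
#'
#' @param alpha_tot Effective equivalent heat transfer coefficient summing
#'   conductive, convective and radiative exchange with the surroundings
#'   (W m^-2 K^-1 semantics). Positive.
#' @param rho Density, kg m^-3. Positive.
#' @param c Specific heat. Treated as an opaque positive factor; no unit
#'   algebra is enforced.
#' @param v_over_a Volume-to-surface-area ratio, m. Positive.
#' @return Decay rate in the units implied by the inputs.
#' @examples
#' theoretical_rdk(alpha_tot = 10, rho = 1000, c = 4000, v_over_a = 0.1)
#' @export
theoretical_rdk <- function(alpha_tot, rho, c, v_over_a) {
  if (any(c(alpha_tot, rho, c, v_over_a) <= 0, na.rm = TRUE)) {
    abort("All thermal properties must be strictly positive.",
          class = "thermdecay_domain_error")
  }
  alpha_tot / (rho * c * v_over_a)
}

#' Bias of the decay rate estimator under non-negligible ambient temperature
#'
#' The ratio estimator `ln(T_d/T_n)/delta_t` drops the ambient-temperature
#' term of the exact cooling solution. This function quantifies the
#' resulting bias for a known cooling state: it simulates exact Newtonian
#' cooling over `delta_t`, applies the estimator to the two endpoint
#' temperatures, and returns estimate minus truth.
#'
#' The bias is exactly zero when `t_ambient = 0` and is negative (the
#' estimator understates the true rate) when `t_ambient > 0`, growing in
#' magnitude with `t_ambient / t0`.
#'
#' @param t0 Initial (daytime) temperature, Kelvin.
#' @param t_ambient Ambient temperature cooled toward, Kelvin.
#' @param k True decay constant, 1/hr.
#' @param delta_t Elapsed time between the two samples, hours.
#' @return Estimated minus true decay rate, 1/hr. Vectorized.
#' @examples
#' approximation_bias(t0 = 310, t_ambient = 280, k = 0.05, delta_t = 12)
#' approximation_bias(310, 0, 0.05, 12)  # exactly 0
#' @export
approximation_bias <- function(t0, t_ambient, k, delta_t = 12) {
  if (any(delta_t <= 0, na.rm = TRUE)) {
    abort("`delta_t` must be positive.", class = "thermdecay_domain_error")
  }
  t_end <- exact_cooling(delta_t, t0, t_ambient, k)
  log(t0 / t_end) / delta_t - k
}
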