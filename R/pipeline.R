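#' Run configuration
#'
#' Assembles the configuration a pipeline command runs from. Precedence is
#' explicit arguments (CLI flags) over the config file over package
#' defaults; the resolved configuration is echoed to the run log.
#'
#' The config file is flat `key: value` YAML. Recognized keys mirror the
#' argument names below.
#'
#' @param file Optional path to a flat `key: value` config file.
#' @param ... Named overrides (highest precedence).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    out_dir = "rdk_output",
    manifest = NULL,
    platform = "aqua",
    day_hour = NA_real_, night_hour = NA_real_,
    delta_t = 12,
    min_pairs = 10,
    min_n = 10,
    mask_warm_nights = FALSE,
    map_path = NULL, map_threshold = 100,
    p_high = 0.05, p_moderate = 0.1,
    continuity = TRUE, tie_correction = TRUE,
    invert_trend = FALSE,
    # simulate
    n_rows = 40, n_cols = 40, years = "2003:2017", n_composites = 46,
    k_min = 0.005, k_max = 0.03, t_ambient = 285, t_peak = 310,
    trend_slope = 0, cloud_fraction = 0, noise_sd = 0, seed = NA_integer_
  )
  from_file <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      abort(sprintf("Config file not found: %s", file),
            class = "thermdecay_config_error")
    }
    from_file <- yaml::read_yaml(file)
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), overrides)
  if (is.character(cfg$years)) cfg$years <- eval(parse(text = cfg$years))
  class(cfg) <- "run_config"
  cfg
}

config_schedule <- function(cfg) {
  if (!is.na(cfg$day_hour) && !is.na(cfg$night_hour)) {
    overpass_schedule(day_hour = cfg$day_hour, night_hour = cfg$night_hour)
  } else {
    overpass_schedule(cfg$platform)
  }
}

log_lines <- function(dir, ..., file = "run.log") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   unlist(list(...)))
  cat(lines, sep = "\n")
  cat(lines, file = file.path(dir, file), sep = "\n", append = TRUE)
}

config_echo <- function(cfg) {
  keep <- !vapply(cfg, is.null, logical(1))
  vals <- vapply(cfg[keep], function(v) paste(format(v), collapse = " "),
                 character(1))
  c(sprintf("thermdecay %s, config hash %s", packageVersion("thermdecay"),
            rlang::hash(cfg)),
    sprintf("  %s = %s", names(cfg)[keep], vals))
}

#' Write a simulated scene to disk
#'
#' One ASCII grid per date per role (`day_<label>.asc`,
#' `night_<label>.asc`), the ground-truth decay field
#' (`truth_k_synthetic.asc` — synthetic, it has no real-data counterpart), a
#' CSV manifest (`path, date, role`) pairing the files, and a JSON manifest
#' of the generating parameters and seed.
#'
#' @param scene A [make_scene()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "sim_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- scene$grid
  rows <- list()
  for (j in seq_len(nrow(scene$dates))) {
    lab <- scene$dates$label[j]
    for (role in c("day", "night")) {
      fn <- sprintf("%s_%s.asc", role, lab)
      write_ascii_grid(scene[[role]][, , j], file.path(dir, fn), grid = g)
      rows[[length(rows) + 1]] <- tibble::tibble(path = fn, date = lab,
                                                role = role)
    }
  }
  write_ascii_grid(scene$truth_k, file.path(dir, "truth_k_synthetic.asc"),
                   grid = g)
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(scene$params,
      list(seed = scene$seed, n_rows = g$n_rows, n_cols = g$n_cols,
           platform = scene$schedule$platform_label,
           day_hour = scene$schedule$day_hour,
           night_hour = scene$schedule$night_hour)),
    file.path(dir, "scene_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Pipeline command: simulate a scene
#'
#' Generates a synthetic multi-year day/night temperature scene from the
#' configuration and writes it file-by-file so the downstream commands can
#' be exercised file-in/file-out.
#'
#' @param cfg A [run_config()]. Uses `n_rows`, `n_cols`, `years`,
#'   `n_composites`, `k_min`/`k_max`, `t_ambient`, `t_peak`, `trend_slope`,
#'   `cloud_fraction`, `noise_sd`, `seed`, the overpass settings and
#'   `out_dir`.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if ((cfg$cloud_fraction > 0 || cfg$noise_sd > 0) && is.na(cfg$seed)) {
    abort("`seed` is required for a stochastic simulation.",
          class = "thermdecay_config_error")
  }
  scene <- make_scene(
    n_rows = cfg$n_rows, n_cols = cfg$n_cols, years = cfg$years,
    n_composites = cfg$n_composites, k_range = c(cfg$k_min, cfg$k_max),
    t_ambient = cfg$t_ambient, t_peak = cfg$t_peak,
    trend_slope = cfg$trend_slope, cloud_fraction = cfg$cloud_fraction,
    noise_sd = cfg$noise_sd, schedule = config_schedule(cfg),
    seed = if (is.na(cfg$seed)) NULL else cfg$seed
  )
  write_scene(scene, cfg$out_dir)
  log_lines(cfg$out_dir, config_echo(cfg),
            sprintf("simulate: wrote %d dates x day/night to %s",
                    nrow(scene$dates), cfg$out_dir))
  invisible(cfg$out_dir)
}

read_manifest <- function(cfg) {
  if (is.null(cfg$manifest) || !file.exists(cfg$manifest)) {
    abort("A `manifest` CSV (path, date, role) is required.",
          class = "thermdecay_config_error")
  }
  man <- tibble::as_tibble(read.csv(cfg$manifest,
                                    stringsAsFactors = FALSE))
  if (!all(c("path", "date", "role") %in% names(man)) || nrow(man) == 0) {
    abort("Manifest must be a non-empty CSV with path, date, role columns.",
          class = "thermdecay_config_error")
  }
  man$path <- ifelse(file.exists(man$path), man$path,
                     file.path(dirname(cfg$manifest), man$path))
  man
}

#' Pipeline command: annual decay rate maps
#'
#' Reads the day/night temperature stacks listed in the manifest, pairs the
#' layers by composite date (unpaired dates are logged and dropped), applies
#' the per-pixel annual decay rate estimator, and writes one decay rate map
#' and one valid-pair-count map per year.
#'
#' @param cfg A [run_config()] with `manifest`, `delta_t`, `min_pairs`,
#'   `mask_warm_nights`, `out_dir`.
#' @return Tibble of written files (year, rdk path, n_pairs path),
#'   invisibly.
#' @export
cmd_annual_rdk <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  man <- read_manifest(cfg)
  wide <- tidyr::pivot_wider(man, id_cols = "date", names_from = "role",
                             values_from = "path")
  if (!all(c("day", "night") %in% names(wide))) {
    abort("Manifest must list both day and night rasters.",
          class = "thermdecay_data_error")
  }
  unpaired <- sum(is.na(wide$day) | is.na(wide$night))
  paired <- wide[!is.na(wide$day) & !is.na(wide$night), ]
  paired <- paired[order(paired$date), ]
  if (nrow(paired) == 0) {
    abort("No paired day/night dates in the manifest.",
          class = "thermdecay_data_error")
  }
  day <- read_stack(paired$day, time_labels = paired$date,
                    check_kelvin = TRUE, variable_name = "lst_day",
                    units = "K")
  night <- read_stack(paired$night, time_labels = paired$date,
                      check_kelvin = TRUE, variable_name = "lst_night",
                      units = "K")
  res <- rdk_annual_map(day, night, delta_t = cfg$delta_t,
                        min_pairs = cfg$min_pairs,
                        mask_warm_nights = cfg$mask_warm_nights)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  years <- res$rdk$time_labels
  files <- tibble::tibble(
    year = years,
    rdk = file.path(cfg$out_dir, sprintf("rdk_%s.asc", years)),
    n_pairs = file.path(cfg$out_dir, sprintf("npairs_%s.asc", years))
  )
  for (j in seq_along(years)) {
    write_ascii_grid(res$rdk, files$rdk[j], layer = j)
    write_ascii_grid(res$n_pairs, files$n_pairs[j], layer = j)
  }
  valid_px <- vapply(seq_along(years),
                     function(j) sum(!is.na(stack_layer(res$rdk, j))),
                     numeric(1))
  log_lines(cfg$out_dir, config_echo(cfg),
            sprintf("annual-rdk: %d paired dates, %d unpaired dropped",
                    nrow(paired), unpaired),
            sprintf("annual-rdk: warm-night fraction %.4f",
                    res$warm_night_frac),
            sprintf("annual-rdk: year %s -> %d valid pixels",
                    years, valid_px))
  invisible(files)
}

#' Pipeline command: trend classification
#'
#' Reads annual decay rate maps (files named `rdk_<year>.asc` under
#' `manifest`'s directory, or an explicit vector in `cfg$rdk_files`), runs
#' the per-pixel Mann-Kendall classification, and writes the class raster
#' (integer codes 1..5, south-to-north of [trend_class_levels]), a
#' `trend_class_legend.csv` code/label/color sidecar and a per-class pixel
#' count CSV.
#'
#' @param cfg A [run_config()] with `out_dir`, `min_n`, the MK toggles, the
#'   significance thresholds, optionally `rdk_dir` (directory holding
#'   `rdk_*.asc`), `map_path`/`map_threshold` for aridity masking, and
#'   `invert_trend`.
#' @return The trend_map result, invisibly.
#' @export
cmd_trend <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  files <- if (!is.null(cfg$rdk_files)) {
    cfg$rdk_files
  } else if (!is.null(cfg$rdk_dir)) {
    sort(list.files(cfg$rdk_dir, "^rdk_.*\\.asc$", full.names = TRUE))
  } else {
    abort("Give `rdk_dir` or `rdk_files` pointing at annual rdk maps.",
          class = "thermdecay_config_error")
  }
  if (length(files) < cfg$min_n) {
    abort(sprintf("%d annual maps found but min_n = %d.", length(files),
                  cfg$min_n),
          class = "thermdecay_data_error")
  }
  stack <- read_stack(files, variable_name = "rdk", units = "1/hr")
  if (!is.null(cfg$map_path)) {
    map <- read_ascii_grid(cfg$map_path)
    if (!grids_identical(map$grid, stack$grid)) {
      map <- regrid(map, stack$grid)
    }
    stack <- mask_by_threshold(stack, map, threshold = cfg$map_threshold)
  }
  res <- trend_map(stack, min_n = cfg$min_n, continuity = cfg$continuity,
                   tie_correction = cfg$tie_correction,
                   p_high = cfg$p_high, p_moderate = cfg$p_moderate,
                   invert = cfg$invert_trend)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(res$classes, file.path(cfg$out_dir, "trend_class.asc"))
  legend <- tibble::tibble(
    code = seq_along(trend_class_levels),
    label = trend_class_levels,
    color = c("#1a9641", "#a6d96a", "#f7f7f7", "#fdae61", "#d7191c")
  )
  write.csv(legend, file.path(cfg$out_dir, "trend_class_legend.csv"),
            row.names = FALSE)
  write.csv(res$counts, file.path(cfg$out_dir, "trend_class_counts.csv"),
            row.names = FALSE)
  log_lines(cfg$out_dir, config_echo(cfg),
            sprintf("trend: %d annual layers, classes %s", length(files),
                    paste(res$counts$class, res$counts$n, sep = "=",
                          collapse = ", ")))
  invisible(res)
}

#' Pipeline command: cross-correlation table
#'
#' Reads the single-band variable rasters named in a `name,path` CSV
#' manifest, harmonizes them onto the grid of the first variable (nearest
#' neighbor downscaling / block-mean upscaling as appropriate), applies the
#' precipitation mask when configured, and writes Pearson and Spearman
#' correlation CSVs over the jointly valid pixels.
#'
#' @param cfg A [run_config()] with `manifest` (name,path CSV), `out_dir`,
#'   optional `map_path`/`map_threshold`, optional `absolute` (variable
#'   names entered as absolute values, e.g. latitude).
#' @return The [correlation_table()], invisibly.
#' @export
cmd_correlate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$manifest) || !file.exists(cfg$manifest)) {
    abort("A `manifest` CSV (name, path) is required.",
          class = "thermdecay_config_error")
  }
  man <- tibble::as_tibble(read.csv(cfg$manifest, stringsAsFactors = FALSE))
  if (!all(c("name", "path") %in% names(man)) || nrow(man) < 2) {
    abort("Manifest must be a CSV with name, path columns (>= 2 variables).",
          class = "thermdecay_config_error")
  }
  man$path <- ifelse(file.exists(man$path), man$path,
                     file.path(dirname(cfg$manifest), man$path))
  layers <- list()
  ref_grid <- NULL
  for (j in seq_len(nrow(man))) {
    r <- tryCatch(read_ascii_grid(man$path[j]), error = function(e) {
      abort(sprintf("Failed reading variable '%s': %s", man$name[j],
                    conditionMessage(e)),
            class = "thermdecay_data_error")
    })
    if (is.null(ref_grid)) ref_grid <- r$grid
    if (!grids_identical(r$grid, ref_grid)) {
      r <- tryCatch(regrid(r, ref_grid), error = function(e) {
        abort(sprintf("Grid harmonization failed for variable '%s': %s",
                      man$name[j], conditionMessage(e)),
              class = "thermdecay_data_error")
      })
      log_lines(cfg$out_dir, sprintf("correlate: regridded '%s' onto %s",
                                     man$name[j], format(ref_grid)))
    }
    layers[[man$name[j]]] <- stack_layer(r, 1)
  }
  if (!is.null(cfg$map_path)) {
    map <- read_ascii_grid(cfg$map_path)
    if (!grids_identical(map$grid, ref_grid)) map <- regrid(map, ref_grid)
    keep <- stack_layer(map, 1) > cfg$map_threshold
    keep[is.na(keep)] <- FALSE
    layers <- lapply(layers, function(m) {
      m[!keep] <- NA_real_
      m
    })
    log_lines(cfg$out_dir,
              sprintf("correlate: MAP > %g mask retained %d pixels",
                      cfg$map_threshold, sum(keep)))
  }
  ct <- correlation_table(layers, absolute = cfg$absolute)
  write_correlation_csv(ct, cfg$out_dir)
  log_lines(cfg$out_dir, config_echo(cfg),
            sprintf("correlate: %d variables over common grid %s",
                    length(layers), format(ref_grid)))
  invisible(ct)
}
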