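#' Run configuration for the command front ends
#'
#' Aggregates every knob of the shape/profile pipeline with explicit
#' defaults.  All resolved values are printed by the commands when
#' `verbose = TRUE`, so a run is reconstructible from its log.
#'
#' @param peak_list_path Path to a peak-list file (see [read_peak_list()]).
#' @param spectrometer_mhz Spectrometer frequency, MHz (required for ppm peak
#'   lists).
#' @param transmitter_ppm Transmitter position on the ppm scale.
#' @param peak_rf_hz Peak RF amplitude, Hz; the retained experimental
#'   presaturation level of 11.7 Hz by default.
#' @param n_points Slices per module (default 50000).
#' @param threshold_rad Per-slice precession-angle threshold (default pi/15).
#' @param module_duration_s Optional override: impose the module duration and
#'   derive `dt = module_duration_s / n_points` instead of using the
#'   threshold rule.
#' @param relaxation_delay_s Total presaturation time, seconds.
#' @param n_modules Optional explicit module count (overrides the delay/T
#'   integer-ratio rule).
#' @param t1_s,t2_s Relaxation times, seconds.
#' @param grid_min_hz,grid_max_hz,grid_step_hz Offset grid for the profile,
#'   Hz, relative to the auxiliary carrier.
#' @param shape_out,profile_out Output paths.
#' @param verbose Print per-step detail.
#' @return An object of class `"run_config"` (a validated list).
#' @export
run_config <- function(peak_list_path = NULL,
                       spectrometer_mhz = NULL,
                       transmitter_ppm = 0,
                       peak_rf_hz = 11.7,
                       n_points = 50000L,
                       threshold_rad = pi / 15,
                       module_duration_s = NULL,
                       relaxation_delay_s = 5,
                       n_modules = NULL,
                       t1_s = 0.5, t2_s = 0.5,
                       grid_min_hz = -50, grid_max_hz = 50, grid_step_hz = 1,
                       shape_out = "presat_shape.txt",
                       profile_out = "presat_profile.csv",
                       verbose = FALSE) {
  cfg <- list(peak_list_path = peak_list_path,
              spectrometer_mhz = spectrometer_mhz,
              transmitter_ppm = transmitter_ppm,
              peak_rf_hz = peak_rf_hz,
              n_points = n_points,
              threshold_rad = threshold_rad,
              module_duration_s = module_duration_s,
              relaxation_delay_s = relaxation_delay_s,
              n_modules = n_modules,
              t1_s = t1_s, t2_s = t2_s,
              grid_min_hz = grid_min_hz, grid_max_hz = grid_max_hz,
              grid_step_hz = grid_step_hz,
              shape_out = shape_out, profile_out = profile_out,
              verbose = isTRUE(verbose))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(name, positive = FALSE, allow_null = FALSE) {
    x <- cfg[[name]]
    if (is.null(x)) {
      if (allow_null) return(invisible())
      stop_config(sprintf("config field '%s' is required", name))
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop_config(sprintf("config field '%s' must be a finite number", name))
    if (positive && x <= 0)
      stop_config(sprintf("config field '%s' must be > 0", name))
  }
  chk("peak_rf_hz", positive = TRUE)
  chk("n_points", positive = TRUE)
  chk("threshold_rad", positive = TRUE)
  chk("module_duration_s", positive = TRUE, allow_null = TRUE)
  chk("relaxation_delay_s", positive = TRUE, allow_null = TRUE)
  chk("n_modules", positive = TRUE, allow_null = TRUE)
  chk("t1_s", positive = TRUE)
  chk("t2_s", positive = TRUE)
  chk("spectrometer_mhz", positive = TRUE, allow_null = TRUE)
  chk("transmitter_ppm")
  chk("grid_min_hz"); chk("grid_max_hz"); chk("grid_step_hz", positive = TRUE)
  if (cfg$grid_min_hz >= cfg$grid_max_hz)
    stop_config("grid_min_hz must be smaller than grid_max_hz")
  structure(cfg, class = "run_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment;
#' keys are the argument names of [run_config()].  Values given as `...`
#' arguments override the file (mirroring CLI-flag precedence).
#'
#' @param path Path to the config file.
#' @param ... Overrides, as named [run_config()] arguments.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  vals <- list()
  numeric_keys <- c("spectrometer_mhz", "transmitter_ppm", "peak_rf_hz",
                    "n_points", "threshold_rad", "module_duration_s",
                    "relaxation_delay_s", "n_modules", "t1_s", "t2_s",
                    "grid_min_hz", "grid_max_hz", "grid_step_hz")
  string_keys <- c("peak_list_path", "shape_out", "profile_out")
  for (i in keep) {
    ln <- trimws(stripped[i])
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop_parse(sprintf("%s: line %d: expected 'key = value', found '%s'",
                         path, i, ln))
    key <- m[2]; val <- trimws(m[3])
    if (key %in% numeric_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop_parse(sprintf("%s: line %d: '%s' must be numeric, found '%s'",
                           path, i, key, val))
      vals[[key]] <- num
    } else if (key %in% string_keys) {
      vals[[key]] <- val
    } else if (key == "verbose") {
      vals[[key]] <- tolower(val) %in% c("true", "1", "yes")
    } else {
      stop_parse(sprintf("%s: line %d: unknown config key '%s'", path, i, key))
    }
  }
  vals <- modifyList(vals, list(...))
  do.call(run_config, vals)
}
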