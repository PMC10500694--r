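# Command front ends: thin, deterministic pipelines over the module API.
# The inst/exec/presat script maps these onto shell subcommands.

cfg_message <- function(cfg, ...) {
  message(sprintf(...))
  invisible(NULL)
}

log_resolved_config <- function(cfg) {
  flat <- cfg[!vapply(cfg, is.null, logical(1))]
  for (k in names(flat))
    cfg_message(cfg, "  config %-20s = %s", k, paste(flat[[k]], collapse = ", "))
}

build_waveform_from_config <- function(cfg) {
  if (is.null(cfg$peak_list_path))
    stop_config("'peak_list_path' is required")
  peaks <- read_peak_list(cfg$peak_list_path)
  if (peaks$unit == "ppm" && is.null(cfg$spectrometer_mhz))
    stop_config("peak list is in ppm: 'spectrometer_mhz' is required")
  plan <- plan_carrier(peaks$positions, unit = peaks$unit,
                       spectrometer_mhz = cfg$spectrometer_mhz,
                       transmitter_ppm = cfg$transmitter_ppm)
  timing <- if (!is.null(cfg$module_duration_s)) {
    choose_timing_from_duration(cfg$module_duration_s, cfg$n_points)
  } else if (max(abs(plan$site_offsets_hz)) == 0) {
    stop_config(paste0(
      "single-site peak list degenerates to CW presaturation: the ",
      "precession-angle rule cannot set dt; supply 'module_duration_s'"))
  } else {
    choose_timing(plan, n_points = cfg$n_points,
                  threshold_rad = cfg$threshold_rad)
  }
  waveform <- synthesize_waveform(plan, peak_rf_hz = cfg$peak_rf_hz,
                                  n_points = timing$n_points,
                                  dt_s = timing$dt_s)
  list(peaks = peaks, plan = plan, timing = timing, waveform = waveform)
}

#' Build and write the presaturation shaped pulse
#'
#' Pipeline: read peak list, plan the auxiliary carrier, choose the slice
#' timing, synthesize the waveform (see [synthesize_waveform()]) and write
#' the shape file.  Prints the shaped-pulse offset, slice duration, module
#' duration and per-site offsets.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `plan`, `timing`, `waveform` and
#'   `shape_path`.
#' @export
cmd_shape <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$verbose) log_resolved_config(cfg)
  parts <- build_waveform_from_config(cfg)
  write_shape_file(parts$waveform, cfg$shape_out)
  cfg_message(cfg, "shape: %d sites, shape offset %.6g Hz",
              parts$plan$n_sites, parts$plan$shape_offset_hz)
  cfg_message(cfg, "shape: dt = %.6g s, module duration T = %.6g s, N = %d",
              parts$timing$dt_s, parts$timing$module_duration_s,
              parts$timing$n_points)
  cfg_message(cfg, "shape: site offsets [Hz]: %s",
              paste(sprintf("%.6g", parts$plan$site_offsets_hz), collapse = ", "))
  cfg_message(cfg, "shape: written to %s", cfg$shape_out)
  invisible(c(parts, list(shape_path = cfg$shape_out)))
}

#' Simulate the saturation profile and per-site suppression figures
#'
#' Builds the waveform as in [cmd_shape()], simulates the saturation profile
#' on the configured grid (relative to the auxiliary carrier), writes it as
#' CSV, and reports the attenuation and 50 %-bandwidth for every site.
#' Per-site figures are measured on a dedicated local grid (site +/- 50 Hz at
#' the configured step), mirroring the experimental procedure of stepping the
#' auxiliary frequency around one resonance.  When `verbose`, the
#' union-of-intervals bandwidth (satellite dips included) is reported next to
#' the contiguous one.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `profile` (grid profile), `sites` (data
#'   frame of per-site attenuation and bandwidths) and `profile_path`.
#' @export
cmd_profile <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$verbose) log_resolved_config(cfg)
  parts <- build_waveform_from_config(cfg)
  wf <- parts$waveform
  relax <- relaxation_params(cfg$t1_s, cfg$t2_s)
  grid <- seq(cfg$grid_min_hz, cfg$grid_max_hz, by = cfg$grid_step_hz)
  req <- profile_request(wf, relax, offset_grid_hz = grid,
                         relaxation_delay_s = cfg$relaxation_delay_s,
                         n_modules = cfg$n_modules)
  profile <- simulate_profile(req)
  write_profile_csv(profile, cfg$profile_out)
  cfg_message(cfg, "profile: %d offsets, %d modules of %.6g s, written to %s",
              length(grid), req$n_modules, wf$module_duration_s,
              cfg$profile_out)

  sites <- data.frame(site_offset_hz = wf$site_offsets_hz,
                      attenuation_percent = NA_real_,
                      bandwidth_hz = NA_real_,
                      bandwidth_union_hz = NA_real_)
  for (i in seq_len(nrow(sites))) {
    s <- sites$site_offset_hz[i]
    local_grid <- seq(s - 50, s + 50, by = cfg$grid_step_hz)
    lp <- simulate_profile(profile_request(wf, relax,
                                           offset_grid_hz = local_grid,
                                           n_modules = req$n_modules))
    sites$attenuation_percent[i] <- attenuation_percent(lp, s)
    sites$bandwidth_hz[i] <- bandwidth_at_half(lp, s)
    sites$bandwidth_union_hz[i] <- bandwidth_at_half(lp, s, rule = "union")
    if (cfg$verbose) {
      cfg_message(cfg,
        "profile: site %+.6g Hz: attenuation %.2f %%, bandwidth %s Hz (union %s Hz)",
        s, sites$attenuation_percent[i],
        format(sites$bandwidth_hz[i]), format(sites$bandwidth_union_hz[i]))
    } else {
      cfg_message(cfg, "profile: site %+.6g Hz: attenuation %.2f %%, bandwidth %s Hz",
                  s, sites$attenuation_percent[i], format(sites$bandwidth_hz[i]))
    }
  }
  invisible(list(profile = profile, sites = sites,
                 profile_path = cfg$profile_out,
                 plan = parts$plan, waveform = wf))
}

#' Fast internal consistency check
#'
#' Runs a reduced-size invariant suite: rotation-matrix orthogonality,
#' recovery of the stationary CW saturation value by long propagation,
#' shape-file round trip, and the mirror symmetry of Mz in the offset sign.
#' Prints a pass/fail table.
#'
#' @param seed Seed for the randomized rotation check.
#' @return Invisibly, `TRUE` when every check passed.
#' @export
cmd_selfcheck <- function(seed = 1L) {
  checks <- list()

  set.seed(seed)
  dev <- 0
  for (i in 1:200) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    R <- rotation_matrix(list(ux = u[1], uy = u[2], uz = u[3],
                              theta = stats::runif(1, -10, 10)))
    dev <- max(dev, max(abs(crossprod(R) - diag(3))), abs(det(R) - 1))
  }
  checks[["rotation orthogonality (200 random)"]] <- dev <= 1e-12

  relax <- relaxation_params(0.5, 0.5)
  wf <- synthesize_waveform(0, peak_rf_hz = 11.7, n_points = 2500,
                            dt_s = 1e-4)
  m <- propagate_waveform(equilibrium_state(), wf, omega0 = 0, relax,
                          n_repeats = 40L)  # 10 s = 20 T1
  checks[["stationary CW saturation recovery"]] <-
    abs(m$mz - stationary_mz(11.7, relax)) <= 1e-3

  wf2 <- synthesize_waveform(c(-40, 40), peak_rf_hz = 50, n_points = 64,
                             dt_s = 2e-4)
  tmp <- tempfile(fileext = ".shape")
  on.exit(unlink(tmp))
  write_shape_file(wf2, tmp)
  back <- as_waveform(read_shape_file(tmp))
  checks[["shape-file round trip"]] <-
    max(abs(back$w1x - wf2$w1x), abs(back$w1y - wf2$w1y)) <=
      1e-6 * 2 * pi * wf2$peak_rf_hz
  ap <- waveform_to_amplitude_phase(wf2)
  bp <- waveform_to_amplitude_phase(back)
  checks[["shape-file amplitude/phase 1e-6"]] <-
    max(abs(ap$amplitude_percent - bp$amplitude_percent),
        abs(ap$phase_deg - bp$phase_deg)) <= 1e-6

  mp <- propagate_waveform(equilibrium_state(), wf2, omega0 = 2 * pi * 17,
                           relax, n_repeats = 5L)
  mm <- propagate_waveform(equilibrium_state(), wf2, omega0 = -2 * pi * 17,
                           relax, n_repeats = 5L)
  checks[["Mz mirror symmetry in offset sign"]] <- abs(mp$mz - mm$mz) <= 1e-12

  width <- max(nchar(names(checks)))
  for (nm in names(checks))
    message(sprintf("  %-*s  %s", width, nm,
                    if (isTRUE(checks[[nm]])) "PASS" else "FAIL"))
  ok <- all(vapply(checks, isTRUE, logical(1)))
  message(if (ok) "selfcheck: all checks passed" else "selfcheck: FAILURES detected")
  invisible(ok)
}
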