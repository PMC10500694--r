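#' Auxiliary-carrier plan from solvent peak positions
#'
#' The auxiliary carrier is the midpoint of the highest and lowest solvent
#' resonance frequencies; per-site saturation offsets are taken relative to
#' it, and the shaped-pulse offset is the difference between the auxiliary
#' carrier and the actual transmitter frequency.
#'
#' Positions may be given directly in Hz (relative to the transmitter) or in
#' ppm together with the spectrometer frequency; ppm-to-Hz conversion uses
#' `hz = ppm * spectrometer_mhz` (one Hz per ppm per MHz), with the
#' transmitter position supplied on the same ppm scale.
#'
#' @param positions Numeric vector of peak positions (>= 1).
#' @param unit `"hz"` or `"ppm"`.
#' @param spectrometer_mhz Spectrometer frequency in MHz (required for ppm).
#' @param transmitter_ppm Transmitter position on the ppm scale (ppm input).
#' @param transmitter_hz Transmitter offset in Hz (Hz input; default 0).
#' @return An object of class `"carrier_plan"` with fields `transmitter_hz`,
#'   `aux_carrier_hz`, `shape_offset_hz`, `site_offsets_hz`, `n_sites`.
#' @export
#' @examples
#' plan_carrier(c(100, 300))                      # aux = 200 Hz
#' plan_carrier(c(63.66, 73.09), unit = "ppm",
#'              spectrometer_mhz = 150.91)        # glycerol
plan_carrier <- function(positions, unit = c("hz", "ppm"),
                         spectrometer_mhz = NULL, transmitter_ppm = 0,
                         transmitter_hz = 0) {
  unit <- match.arg(unit)
  if (length(positions) < 1L)
    stop_invalid("at least one peak position is required")
  if (!is.numeric(positions) || !all(is.finite(positions)))
    stop_invalid("peak positions must be finite numbers")
  if (unit == "ppm") {
    if (is.null(spectrometer_mhz))
      stop_config("ppm peak positions require 'spectrometer_mhz'")
    check_scalar(spectrometer_mhz, "spectrometer_mhz", positive = TRUE)
    check_scalar(transmitter_ppm, "transmitter_ppm")
    peaks_hz <- positions * spectrometer_mhz
    transmitter_hz <- transmitter_ppm * spectrometer_mhz
  } else {
    check_scalar(transmitter_hz, "transmitter_hz")
    peaks_hz <- positions
  }
  if (anyDuplicated(positions))
    warning("duplicate peak positions: coincident sites add coherently (doubled RF power at that site)",
            call. = FALSE)
  aux <- (max(peaks_hz) + min(peaks_hz)) / 2
  structure(list(
    transmitter_hz = transmitter_hz,
    aux_carrier_hz = aux,
    shape_offset_hz = aux - transmitter_hz,
    site_offsets_hz = peaks_hz - aux,
    n_sites = length(peaks_hz),
    peak_positions = positions,
    unit = unit,
    spectrometer_mhz = if (unit == "ppm") spectrometer_mhz else NULL
  ), class = "carrier_plan")
}

#' @export
print.carrier_plan <- function(x, ...) {
  cat("<carrier_plan>\n")
  cat(sprintf("  sites:            %d\n", x$n_sites))
  cat(sprintf("  aux carrier:      %.6g Hz\n", x$aux_carrier_hz))
  cat(sprintf("  shape offset:     %.6g Hz\n", x$shape_offset_hz))
  cat(sprintf("  site offsets:     %s Hz\n",
              paste(sprintf("%.6g", x$site_offsets_hz), collapse = ", ")))
  invisible(x)
}

#' Slice duration from the precession-angle threshold
#'
#' The slice duration is the largest `dt` such that the per-slice precession
#' angle at the most off-carrier site stays below the threshold:
#' `2*pi*max|site_offset_hz| * dt <= threshold_rad` (default pi/15).  The
#' module duration follows as `T = n_points * dt`.
#'
#' @param site_offsets_hz Per-site saturation offsets, Hz (or a
#'   `"carrier_plan"`).
#' @param n_points Number of slices N per module (default 50000).
#' @param threshold_rad Maximum per-slice precession angle, rad.
#' @return A list with `dt_s`, `module_duration_s`, `n_points`,
#'   `threshold_rad`.
#' @seealso [choose_timing_from_duration()] for the degenerate all-zero-offset
#'   (single-site) case, or to impose a module duration directly.
#' @export
#' @examples
#' choose_timing(c(-100, 100), n_points = 50000)  # dt ~ 3.33e-4 s
choose_timing <- function(site_offsets_hz, n_points = 50000L,
                          threshold_rad = pi / 15) {
  if (inherits(site_offsets_hz, "carrier_plan"))
    site_offsets_hz <- site_offsets_hz$site_offsets_hz
  if (length(site_offsets_hz) < 1L || !all(is.finite(site_offsets_hz)))
    stop_invalid("site offsets must be a non-empty finite numeric vector")
  check_scalar(n_points, "n_points", positive = TRUE)
  check_scalar(threshold_rad, "threshold_rad", positive = TRUE)
  max_off <- max(abs(site_offsets_hz))
  if (max_off == 0)
    stop_invalid(paste0(
      "all site offsets are zero (single-site / pure CW case): the ",
      "precession-angle criterion cannot set dt; supply the module duration ",
      "explicitly via choose_timing_from_duration()"))
  dt <- threshold_rad / (2 * pi * max_off)
  list(dt_s = dt, module_duration_s = n_points * dt,
       n_points = as.integer(n_points), threshold_rad = threshold_rad)
}

#' Slice duration from an imposed module duration
#'
#' @param module_duration_s Module duration T, seconds (> 0).
#' @param n_points Number of slices N (default 50000).
#' @return A list with `dt_s = T/N`, `module_duration_s`, `n_points`,
#'   `threshold_rad = NA`.
#' @export
#' @examples
#' choose_timing_from_duration(0.5, 50000)  # dt = 10 microseconds
choose_timing_from_duration <- function(module_duration_s, n_points = 50000L) {
  check_scalar(module_duration_s, "module_duration_s", positive = TRUE)
  check_scalar(n_points, "n_points", positive = TRUE)
  list(dt_s = module_duration_s / n_points,
       module_duration_s = module_duration_s,
       n_points = as.integer(n_points), threshold_rad = NA_real_)
}

# Sum the per-site phase factors in symmetric pair order (outermost pair
# first) so that for site sets of exact +/- pairs the imaginary parts cancel
# exactly in floating point.  This is only a summation-order choice on the
# literal multi-site sum.
pair_order <- function(offsets) {
  ord <- order(offsets)
  idx <- integer(0)
  i <- 1L; j <- length(ord)
  while (i < j) {
    idx <- c(idx, ord[i], ord[j])
    i <- i + 1L; j <- j - 1L
  }
  if (i == j) idx <- c(idx, ord[i])
  idx
}

#' Synthesize a multisite presaturation waveform
#'
#' Builds the N-slice table of RF field components of a
#' multiple-frequency-shifted laminar pulse: slice `j` (0-based) carries
#' `w1x + i*w1y = (2*pi*peak_rf_hz / n) * sum_k exp(i * 2*pi*offset_k * j*dt)`,
#' evaluated at the slice start time.  RF intensity is equally distributed
#' among the `n` sites and all phases are zero at `t = 0`, so slice 0 always
#' has `(w1x, w1y) = (2*pi*peak_rf_hz, 0)`.
#'
#' @param plan A `"carrier_plan"` or a numeric vector of site offsets in Hz.
#' @param peak_rf_hz Peak RF amplitude `Omega_1/2pi`, Hz (> 0); each site
#'   receives `peak_rf_hz / n`.
#' @param n_points Number of slices N (>= 1).
#' @param dt_s Slice duration, seconds (> 0).
#' @return An object of class `"presat_waveform"`: vectors `w1x`, `w1y`
#'   (rad/s), scalars `dt_s`, `n_points`, `module_duration_s`, `peak_rf_hz`,
#'   `site_offsets_hz`, and (when available from the plan) `shape_offset_hz`.
#' @export
#' @examples
#' tm <- choose_timing(c(-40, 40), n_points = 1000)
#' wf <- synthesize_waveform(c(-40, 40), peak_rf_hz = 50,
#'                           n_points = tm$n_points, dt_s = tm$dt_s)
synthesize_waveform <- function(plan, peak_rf_hz, n_points, dt_s) {
  shape_offset <- NA_real_
  if (inherits(plan, "carrier_plan")) {
    offsets <- plan$site_offsets_hz
    shape_offset <- plan$shape_offset_hz
  } else {
    offsets <- as.numeric(plan)
  }
  if (length(offsets) < 1L || !all(is.finite(offsets)))
    stop_invalid("site offsets must be a non-empty finite numeric vector")
  check_scalar(peak_rf_hz, "peak_rf_hz", positive = TRUE)
  check_scalar(n_points, "n_points", positive = TRUE)
  if (n_points != round(n_points)) stop_invalid("'n_points' must be an integer")
  check_scalar(dt_s, "dt_s", positive = TRUE)

  n <- length(offsets)
  t <- (seq_len(n_points) - 1) * dt_s
  sum_c <- numeric(n_points)
  sum_s <- numeric(n_points)
  for (k in pair_order(offsets)) {
    ph <- (2 * pi * offsets[k]) * t
    sum_c <- sum_c + cos(ph)
    sum_s <- sum_s + sin(ph)
  }
  scale <- 2 * pi * peak_rf_hz
  w1x <- scale * (sum_c / n)
  w1y <- scale * (sum_s / n)

  wf <- structure(list(
    w1x = w1x, w1y = w1y, dt_s = dt_s, n_points = as.integer(n_points),
    module_duration_s = n_points * dt_s, peak_rf_hz = peak_rf_hz,
    site_offsets_hz = offsets, shape_offset_hz = shape_offset
  ), class = "presat_waveform")
  validate_waveform(wf)
}

validate_waveform <- function(wf) {
  amp <- sqrt(wf$w1x^2 + wf$w1y^2)
  cap <- 2 * pi * wf$peak_rf_hz
  if (any(amp > cap * (1 + 1e-12)))
    stop_invalid("slice amplitude exceeds 2*pi*peak_rf_hz")
  if (abs(wf$module_duration_s - wf$n_points * wf$dt_s) >
      1e-12 * wf$module_duration_s)
    stop_invalid("module duration is inconsistent with n_points * dt_s")
  wf
}

#' @export
print.presat_waveform <- function(x, ...) {
  cat("<presat_waveform>\n")
  cat(sprintf("  slices (N):       %d x %.4g us\n", x$n_points, x$dt_s * 1e6))
  cat(sprintf("  module duration:  %.6g s\n", x$module_duration_s))
  cat(sprintf("  peak RF:          %.6g Hz\n", x$peak_rf_hz))
  cat(sprintf("  sites:            %s Hz\n",
              paste(sprintf("%.6g", x$site_offsets_hz), collapse = ", ")))
  invisible(x)
}

#' Convert a waveform to spectrometer amplitude/phase pairs
#'
#' Amplitude is given as a percentage of the peak RF level
#' (`100 * |w1| / (2*pi*peak_rf_hz)`, in `[0, 100]`); phase is `atan2(w1y, w1x)`
#' mapped to degrees in `[0, 360)`.  Zero-amplitude slices get phase 0 by
#' convention.
#'
#' @param w A `"presat_waveform"`.
#' @return A data frame with columns `amplitude_percent`, `phase_deg`.
#' @export
waveform_to_amplitude_phase <- function(w) {
  stopifnot(inherits(w, "presat_waveform"))
  cap <- 2 * pi * w$peak_rf_hz
  amp <- 100 * sqrt(w$w1x^2 + w$w1y^2) / cap
  amp <- pmin(amp, 100)
  phase <- ifelse(amp == 0, 0, atan2(w$w1y, w$w1x) * 180 / pi)
  phase <- phase %% 360
  data.frame(amplitude_percent = amp, phase_deg = phase)
}
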