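#' Stationary on-resonance longitudinal magnetization under CW irradiation
#'
#' For a constant on-resonance RF field the magnetization tends to the
#' stationary value `Mz_stat/Mz_eq = 1 / (1 + (2*pi*peak_rf_hz)^2 * T1 * T2)`.
#'
#' @param peak_rf_hz RF amplitude `Omega_1/2pi`, Hz (>= 0).
#' @param relax A [relaxation_params()].
#' @return Stationary `Mz` as a fraction of `Mz_eq`.
#' @export
#' @examples
#' stationary_mz(11.7, relaxation_params(0.5, 0.5))
stationary_mz <- function(peak_rf_hz, relax) {
  check_scalar(peak_rf_hz, "peak_rf_hz", nonneg = TRUE)
  stopifnot(inherits(relax, "relaxation_params"))
  1 / (1 + (2 * pi * peak_rf_hz)^2 * relax$t1 * relax$t2)
}

#' Stationary Mz under off-resonance CW irradiation
#'
#' Solves the 3x3 linear stationary Bloch system for a constant field
#' `(w1x, 0)` applied at a resonance offset, the off-resonance generalization
#' of [stationary_mz()] (to which it reduces at zero offset).  Used as a
#' long-irradiation oracle for saturation-profile widths.
#'
#' @inheritParams stationary_mz
#' @param offset_hz Resonance offset(s) `Omega_0/2pi`, Hz (vectorized).
#' @return Stationary `Mz` as a fraction of `Mz_eq`, one value per offset.
#' @export
cw_offres_steady_state <- function(peak_rf_hz, offset_hz, relax) {
  check_scalar(peak_rf_hz, "peak_rf_hz", nonneg = TRUE)
  stopifnot(inherits(relax, "relaxation_params"))
  if (!is.numeric(offset_hz) || !all(is.finite(offset_hz)))
    stop_invalid("'offset_hz' must be finite numeric")
  w1 <- 2 * pi * peak_rf_hz
  vapply(offset_hz, function(f0) {
    w0 <- 2 * pi * f0
    # stationary system: R2 mx - w0 my           = 0
    #                    w0 mx + R2 my - w1 mz   = 0
    #                            w1 my + R1 mz   = R1 mz_eq
    A <- matrix(c(relax$r2, -w0, 0,
                  w0, relax$r2, -w1,
                  0, w1, relax$r1), nrow = 3, byrow = TRUE)
    sol <- tryCatch(solve(A, c(0, 0, relax$r1)),
                    error = function(e) stop_numeric(paste0(
                      "stationary Bloch system is singular: ", conditionMessage(e))))
    sol[3]
  }, numeric(1))
}

#' Saturation-profile simulation request
#'
#' Bundles a waveform, relaxation parameters, the presaturation (relaxation
#' delay) duration and the offset grid.  The number of presaturation modules
#' must divide the relaxation delay exactly: `n_modules =
#' relaxation_delay_s / module_duration_s` is required to be an integer
#' (within 1e-6 relative), or may be given directly.
#'
#' @param waveform A `"presat_waveform"`.
#' @param relax A [relaxation_params()].
#' @param offset_grid_hz Strictly increasing, regularly spaced offsets, Hz.
#' @param relaxation_delay_s Total presaturation time, seconds (ignored when
#'   `n_modules` is given).
#' @param n_modules Number of module repetitions (optional).
#' @return An object of class `"profile_request"`.
#' @export
profile_request <- function(waveform, relax, offset_grid_hz,
                            relaxation_delay_s = NULL, n_modules = NULL) {
  stopifnot(inherits(waveform, "presat_waveform"),
            inherits(relax, "relaxation_params"))
  if (length(offset_grid_hz) < 1L || !all(is.finite(offset_grid_hz)))
    stop_invalid("offset grid must be finite numeric")
  if (length(offset_grid_hz) > 1L) {
    d <- diff(offset_grid_hz)
    if (any(d <= 0))
      stop_invalid("offset grid must be strictly increasing")
    if (max(d) - min(d) > 1e-9 * max(abs(d)))
      stop_invalid("offset grid must be regularly spaced")
  }
  if (is.null(n_modules)) {
    if (is.null(relaxation_delay_s))
      stop_config("supply either 'relaxation_delay_s' or 'n_modules'")
    check_scalar(relaxation_delay_s, "relaxation_delay_s", positive = TRUE)
    ratio <- relaxation_delay_s / waveform$module_duration_s
    if (abs(ratio - round(ratio)) > 1e-6 * max(1, ratio) || round(ratio) < 1)
      stop_config(sprintf(
        paste0("relaxation delay (%.6g s) is not an integer number of modules ",
               "(module duration %.6g s, ratio %.6g); adjust the delay, the ",
               "module duration, or pass n_modules directly"),
        relaxation_delay_s, waveform$module_duration_s, ratio))
    n_modules <- as.integer(round(ratio))
  } else {
    check_scalar(n_modules, "n_modules", positive = TRUE)
    if (n_modules != round(n_modules))
      stop_invalid("'n_modules' must be an integer")
    n_modules <- as.integer(n_modules)
    relaxation_delay_s <- n_modules * waveform$module_duration_s
  }
  structure(list(waveform = waveform, relax = relax,
                 offset_grid_hz = as.numeric(offset_grid_hz),
                 relaxation_delay_s = relaxation_delay_s,
                 n_modules = n_modules),
            class = "profile_request")
}

#' Simulate a frequency-domain saturation profile
#'
#' For every offset of the grid, a magnetization vector starting at
#' equilibrium is propagated through `n_modules` repetitions of the waveform
#' and the final longitudinal component is recorded.  Public offsets are in
#' Hz; the conversion to angular frequency happens once, here.
#'
#' @param req A [profile_request()], or a `"presat_waveform"` together with
#'   the remaining arguments of [profile_request()].
#' @param ... When `req` is a waveform: passed on to [profile_request()].
#' @return An object of class `"saturation_profile"`: `offsets_hz`,
#'   `mz_final` (fractions of `mz_eq`) and a `meta` list.
#' @export
#' @examples
#' wf <- synthesize_waveform(c(-40, 40), peak_rf_hz = 50,
#'                           n_points = 500, dt_s = 1e-3)
#' pr <- simulate_profile(wf, relax = relaxation_params(0.5, 0.5),
#'                        offset_grid_hz = seq(-100, 100, 5), n_modules = 10)
simulate_profile <- function(req, ...) {
  if (inherits(req, "presat_waveform"))
    req <- profile_request(req, ...)
  stopifnot(inherits(req, "profile_request"))
  wf <- req$waveform
  tab <- validate_slice_table(slice_table(wf))
  m0 <- equilibrium_state()
  res <- propagate_batch(m0, tab, 2 * pi * req$offset_grid_hz, req$relax,
                         n_repeats = req$n_modules)
  structure(list(
    offsets_hz = req$offset_grid_hz,
    mz_final = res[, "mz"],
    meta = list(peak_rf_hz = wf$peak_rf_hz,
                site_offsets_hz = wf$site_offsets_hz,
                n_points = wf$n_points, dt_s = wf$dt_s,
                module_duration_s = wf$module_duration_s,
                n_modules = req$n_modules,
                relaxation_delay_s = req$relaxation_delay_s,
                t1_s = req$relax$t1, t2_s = req$relax$t2)
  ), class = "saturation_profile")
}

#' @export
print.saturation_profile <- function(x, ...) {
  cat("<saturation_profile>\n")
  cat(sprintf("  grid:      %d offsets, %.6g .. %.6g Hz\n",
              length(x$offsets_hz), min(x$offsets_hz), max(x$offsets_hz)))
  cat(sprintf("  min Mz:    %.4g at %.6g Hz\n",
              min(x$mz_final), x$offsets_hz[which.min(x$mz_final)]))
  cat(sprintf("  delay:     %g s (%d modules of %g s)\n",
              x$meta$relaxation_delay_s, x$meta$n_modules,
              x$meta$module_duration_s))
  invisible(x)
}

#' Signal attenuation at an offset
#'
#' `100 * (1 - Mz)` percent at the requested offset, with linear
#' interpolation between grid points.
#'
#' @param profile A `"saturation_profile"`.
#' @param at_offset_hz Offset at which to evaluate, Hz (within the grid).
#' @return Attenuation in percent.
#' @export
attenuation_percent <- function(profile, at_offset_hz) {
  stopifnot(inherits(profile, "saturation_profile"))
  check_scalar(at_offset_hz, "at_offset_hz")
  if (at_offset_hz < min(profile$offsets_hz) ||
      at_offset_hz > max(profile$offsets_hz))
    stop_invalid(sprintf("offset %.6g Hz lies outside the profile grid [%.6g, %.6g]",
                         at_offset_hz, min(profile$offsets_hz),
                         max(profile$offsets_hz)))
  mz <- approx(profile$offsets_hz, profile$mz_final, xout = at_offset_hz)$y
  100 * (1 - mz)
}

#' Offset intervals with at least a given signal reduction
#'
#' Finds the contiguous runs of the grid where `1 - Mz >= level` and locates
#' their edges by linear interpolation on the flanking segments (grid
#' boundaries are used as-is when a run touches them).
#'
#' @param profile A `"saturation_profile"`.
#' @param level Reduction level (default 0.5, the 50 % criterion).
#' @return A data frame with one row per interval: `left_hz`, `right_hz`,
#'   `center_hz`, `width_hz`, `min_mz`, `at_min_hz`.  Zero rows when the
#'   level is reached nowhere.
#' @export
half_reduction_intervals <- function(profile, level = 0.5) {
  stopifnot(inherits(profile, "saturation_profile"))
  check_scalar(level, "level", positive = TRUE)
  x <- profile$offsets_hz
  red <- 1 - profile$mz_final
  inside <- red >= level
  out <- data.frame(left_hz = numeric(0), right_hz = numeric(0),
                    center_hz = numeric(0), width_hz = numeric(0),
                    min_mz = numeric(0), at_min_hz = numeric(0))
  if (!any(inside)) return(out)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cross <- function(i0, i1) {
    # offset where red crosses `level` between grid points i0 and i1
    x[i0] + (level - red[i0]) * (x[i1] - x[i0]) / (red[i1] - red[i0])
  }
  for (k in which(r$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    left <- if (i1 > 1L) cross(i1 - 1L, i1) else x[1L]
    right <- if (i2 < length(x)) cross(i2 + 1L, i2) else x[length(x)]
    imin <- i1 - 1L + which.min(profile$mz_final[i1:i2])
    out <- rbind(out, data.frame(
      left_hz = left, right_hz = right,
      center_hz = (left + right) / 2, width_hz = right - left,
      min_mz = profile$mz_final[imin], at_min_hz = x[imin]))
  }
  out
}

#' Suppression bandwidth at 50 % signal reduction
#'
#' Width of the offset interval around a saturation site in which the signal
#' intensity is reduced by at least `level` (default 50 %).  With
#' `rule = "contiguous"` (the default) only the contiguous interval nearest
#' the requested site counts; disjoint satellite dips of the wavy
#' close-frequency regime are excluded.  `rule = "union"` instead returns the
#' total measure of all intervals reaching the level.
#'
#' @param profile A `"saturation_profile"`.
#' @param site_offset_hz Saturation-site offset, Hz.
#' @param level Reduction level, default 0.5.
#' @param rule `"contiguous"` or `"union"`.
#' @return Bandwidth in Hz, or `NA_real_` when the reduction level is reached
#'   nowhere on the grid ("not reached" sentinel, not an error).
#' @export
bandwidth_at_half <- function(profile, site_offset_hz, level = 0.5,
                              rule = c("contiguous", "union")) {
  rule <- match.arg(rule)
  check_scalar(site_offset_hz, "site_offset_hz")
  iv <- half_reduction_intervals(profile, level)
  if (nrow(iv) == 0L) return(NA_real_)
  if (rule == "union") return(sum(iv$width_hz))
  dist <- pmax(iv$left_hz - site_offset_hz, site_offset_hz - iv$right_hz, 0)
  iv$width_hz[which.min(dist)]
}

#' Saturation profile as a two-column table
#'
#' @param profile A `"saturation_profile"`.
#' @return A data frame with columns `offset_hz`, `mz_fraction`.
#' @export
profile_to_table <- function(profile) {
  stopifnot(inherits(profile, "saturation_profile"))
  data.frame(offset_hz = profile$offsets_hz, mz_fraction = profile$mz_final)
}

#' Write a saturation profile as CSV
#'
#' Two columns `offset_hz, mz_fraction`, preceded by `#`-prefixed metadata
#' lines recording the waveform, relaxation and delay parameters.
#'
#' @param profile A `"saturation_profile"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "saturation_profile"))
  meta <- profile$meta
  hdr <- c("# presatr saturation profile",
           vapply(names(meta), function(k) {
             sprintf("# %s= %s", k,
                     paste(sprintf("%.17g", meta[[k]]), collapse = ", "))
           }, character(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("offset_hz,mz_fraction", con)
  writeLines(sprintf("%.17g,%.17g", profile$offsets_hz, profile$mz_final), con)
  invisible(path)
}

#' Read a saturation profile written by [write_profile_csv()]
#'
#' @param path Input path.
#' @return A `"saturation_profile"` (metadata restored from the header).
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3)
      meta[[m[2]]] <- suppressWarnings(
        as.numeric(trimws(strsplit(m[3], ",")[[1]])))
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L || body[1] != "offset_hz,mz_fraction")
    stop_parse("missing 'offset_hz,mz_fraction' header row")
  dat <- read.csv(text = body, header = TRUE,
                  colClasses = c("numeric", "numeric"))
  structure(list(offsets_hz = dat$offset_hz, mz_final = dat$mz_fraction,
                 meta = meta),
            class = "saturation_profile")
}
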