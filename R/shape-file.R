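# Shaped-pulse file dialect
#
# A minimal JCAMP-DX-like text format, fixed byte-exactly so that files are
# reproducible and round-trippable:
#
#   ##TITLE= <title>
#   ##JCAMP-DX= 5.00 $$ presatr shaped-pulse dialect v1
#   ##DATA TYPE= Shape Data
#   ##ORIGIN= presatr
#   $$ peak_rf_hz= <value>
#   $$ dt_s= <value>
#   $$ shape_offset_hz= <value>
#   $$ site_offsets_hz= <comma-separated values>
#   ##NPOINTS= <N>
#   <amplitude_percent>, <phase_deg>     (N lines, %.6f each)
#   ##END=
#
# Metadata values are written with 17 significant digits; the body carries
# six decimals, i.e. the documented 1e-6 round-trip precision.

fmt_meta <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a shaped-pulse file
#'
#' Emits the waveform as amplitude/phase pairs in the package's documented
#' JCAMP-DX-like dialect (see the source header of `shape-file.R`), including
#' the shaped-pulse offset and the peak RF level so that the pulse is fully
#' reconstructible from the file alone.  Content is deterministic: no
#' timestamps.
#'
#' @param w A `"presat_waveform"`.
#' @param path Output file path.
#' @param title Title line.
#' @return Invisibly, `path`.
#' @seealso [read_shape_file()], [as_waveform()]
#' @export
write_shape_file <- function(w, path,
                             title = "presatr multisite presaturation shaped pulse") {
  stopifnot(inherits(w, "presat_waveform"))
  ap <- waveform_to_amplitude_phase(w)
  header <- c(
    paste0("##TITLE= ", title),
    "##JCAMP-DX= 5.00 $$ presatr shaped-pulse dialect v1",
    "##DATA TYPE= Shape Data",
    "##ORIGIN= presatr",
    paste0("$$ peak_rf_hz= ", fmt_meta(w$peak_rf_hz)),
    paste0("$$ dt_s= ", fmt_meta(w$dt_s)),
    paste0("$$ shape_offset_hz= ", fmt_meta(w$shape_offset_hz)),
    paste0("$$ site_offsets_hz= ",
           paste(fmt_meta(w$site_offsets_hz), collapse = ", ")),
    paste0("##NPOINTS= ", w$n_points)
  )
  body <- sprintf("%.6f, %.6f", ap$amplitude_percent, ap$phase_deg)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body, "##END="), con)
  invisible(path)
}

#' Read a shaped-pulse file
#'
#' Parses a file in the dialect produced by [write_shape_file()].  Malformed
#' headers or body rows raise a parse error naming the offending line.
#'
#' @param path Input file path.
#' @return An object of class `"presat_shape"`: `amplitude_percent`,
#'   `phase_deg`, `n_points`, `title`, and the metadata `peak_rf_hz`, `dt_s`,
#'   `shape_offset_hz`, `site_offsets_hz` (NA when absent from the file).
#' @export
read_shape_file <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- list(peak_rf_hz = NA_real_, dt_s = NA_real_,
               shape_offset_hz = NA_real_, site_offsets_hz = NA_real_)
  title <- NA_character_
  npoints <- NA_integer_
  amp <- numeric(0); phase <- numeric(0)
  in_body <- FALSE
  ended <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "##TITLE=")) {
      title <- trimws(sub("^##TITLE=", "", ln))
    } else if (startsWith(ln, "##NPOINTS=")) {
      v <- suppressWarnings(as.integer(trimws(sub("^##NPOINTS=", "", ln))))
      if (is.na(v) || v < 1)
        stop_parse(sprintf("line %d: invalid ##NPOINTS value", i))
      npoints <- v
      in_body <- TRUE
    } else if (startsWith(ln, "##END")) {
      ended <- TRUE
      in_body <- FALSE
    } else if (startsWith(ln, "##")) {
      next  # other JCAMP records are ignored
    } else if (startsWith(ln, "$$")) {
      kv <- sub("^\\$\\$\\s*", "", ln)
      m <- regmatches(kv, regexec("^([A-Za-z0-9_]+)=\\s*(.*)$", kv))[[1]]
      if (length(m) == 3 && m[2] %in% names(meta)) {
        toks <- trimws(strsplit(m[3], ",")[[1]])
        vals <- suppressWarnings(as.numeric(toks))
        if (anyNA(vals) && !all(toks[is.na(vals)] == "NA"))
          stop_parse(sprintf("line %d: unreadable numeric metadata '%s'", i, m[2]))
        meta[[m[2]]] <- vals
      }
    } else if (in_body) {
      m <- regmatches(ln, regexec(
        "^([-+0-9.eE]+)\\s*,\\s*([-+0-9.eE]+)$", ln))[[1]]
      if (length(m) != 3)
        stop_parse(sprintf("line %d: malformed amplitude/phase row: '%s'", i, ln))
      a <- suppressWarnings(as.numeric(m[2]))
      p <- suppressWarnings(as.numeric(m[3]))
      if (is.na(a) || is.na(p))
        stop_parse(sprintf("line %d: unreadable amplitude/phase row", i))
      amp <- c(amp, a); phase <- c(phase, p)
    } else {
      stop_parse(sprintf("line %d: unexpected content before ##NPOINTS=: '%s'", i, ln))
    }
  }
  if (is.na(npoints)) stop_parse("missing ##NPOINTS= record")
  if (!ended) stop_parse("missing ##END= record")
  if (length(amp) != npoints)
    stop_parse(sprintf("body has %d rows but ##NPOINTS= %d", length(amp), npoints))
  structure(list(amplitude_percent = amp, phase_deg = phase,
                 n_points = npoints, title = title,
                 peak_rf_hz = meta$peak_rf_hz, dt_s = meta$dt_s,
                 shape_offset_hz = meta$shape_offset_hz,
                 site_offsets_hz = meta$site_offsets_hz),
            class = "presat_shape")
}

#' Reconstruct a waveform from a parsed shape file
#'
#' Converts amplitude/phase pairs back to RF field components using the
#' `peak_rf_hz` and `dt_s` metadata carried by the file.
#'
#' @param shape A `"presat_shape"` from [read_shape_file()].
#' @return A `"presat_waveform"`.
#' @export
as_waveform <- function(shape) {
  stopifnot(inherits(shape, "presat_shape"))
  if (is.na(shape$peak_rf_hz) || is.na(shape$dt_s))
    stop_parse("shape file lacks peak_rf_hz/dt_s metadata; cannot reconstruct field components")
  cap <- 2 * pi * shape$peak_rf_hz
  amp <- shape$amplitude_percent / 100 * cap
  ph <- shape$phase_deg * pi / 180
  structure(list(
    w1x = amp * cos(ph), w1y = amp * sin(ph),
    dt_s = shape$dt_s, n_points = shape$n_points,
    module_duration_s = shape$n_points * shape$dt_s,
    peak_rf_hz = shape$peak_rf_hz,
    site_offsets_hz = shape$site_offsets_hz,
    shape_offset_hz = shape$shape_offset_hz
  ), class = "presat_waveform")
}
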