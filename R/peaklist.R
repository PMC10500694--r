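# Peak-list text format: '#' comment lines anywhere, then a one-line header
# declaring the unit ("ppm" or "hz", optionally as "unit: ppm"), then one
# peak position per line.

#' Read a solvent peak list
#'
#' @param path Path to a peak-list file.
#' @return An object of class `"peak_list"`: `positions` (numeric, in file
#'   order, duplicates preserved), `unit` (`"ppm"` or `"hz"`) and `path`.
#' @export
#' @examples
#' dir <- tempfile(); paths <- make_fixtures(dir)
#' read_peak_list(paths[["glycerol"]])
read_peak_list <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  if (length(keep) == 0L)
    stop_parse(sprintf("%s: no content (empty peak list)", path))
  hdr_i <- keep[1]
  hdr <- tolower(trimws(stripped[hdr_i]))
  m <- regmatches(hdr, regexec("^(unit\\s*[:=]\\s*)?(ppm|hz)$", hdr))[[1]]
  if (length(m) == 0L)
    stop_parse(sprintf(
      "%s: line %d: expected a unit header ('ppm' or 'hz'), found '%s'",
      path, hdr_i, trimws(stripped[hdr_i])))
  unit <- m[3]
  pos <- numeric(0)
  for (i in keep[-1]) {
    v <- suppressWarnings(as.numeric(trimws(stripped[i])))
    if (is.na(v))
      stop_parse(sprintf("%s: line %d: unparseable peak position '%s'",
                         path, i, trimws(stripped[i])))
    pos <- c(pos, v)
  }
  if (length(pos) == 0L)
    stop_parse(sprintf("%s: no peak positions after the unit header", path))
  structure(list(positions = pos, unit = unit, path = path),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks (%s): %s\n", length(x$positions), x$unit,
              paste(x$positions, collapse = ", ")))
  invisible(x)
}

#' Write a peak list
#'
#' @param positions Numeric peak positions.
#' @param unit `"ppm"` or `"hz"`.
#' @param path Output path.
#' @param comment Optional comment line(s) written as `#` lines.
#' @return Invisibly, `path`.
#' @export
write_peak_list <- function(positions, unit = c("ppm", "hz"), path,
                            comment = NULL) {
  unit <- match.arg(unit)
  if (length(positions) < 1L || !all(is.finite(positions)))
    stop_invalid("peak positions must be a non-empty finite numeric vector")
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(unit, con)
  writeLines(sprintf("%.17g", positions), con)
  invisible(path)
}

# 13C chemical shifts (ppm) of the five high-boiling-point extraction
# solvents; the 67.83/67.89 pair of 1,2-propanediol is the close-frequency
# case (0.06 ppm, about 9 Hz at 150.91 MHz) that produces wavy profiles.
solvent_shift_table <- list(
  "glycerol"        = c(63.66, 73.09),
  "12-propanediol"  = c(20.36, 67.83, 67.89),
  "13-propanediol"  = c(36.24, 58.72),
  "12-butanediol"   = c(10.47, 26.68, 66.13, 73.13),
  "13-butanediol"   = c(24.32, 42.40, 58.86, 64.20)
)

#' Reference 13C shifts of the supported heavy solvents
#'
#' @return A named list of numeric ppm vectors (glycerol, 1,2-propanediol,
#'   1,3-propanediol, 1,2-butanediol, 1,3-butanediol).
#' @export
solvent_peak_shifts <- function() solvent_shift_table

#' Write the built-in solvent peak-list fixtures
#'
#' Creates one peak-list file per supported heavy solvent, with the reference
#' 13C chemical shifts of [solvent_peak_shifts()].  Output is deterministic
#' (no timestamps); re-running overwrites identically.
#'
#' @param output_dir Directory (created if needed).
#' @return Invisibly, a named character vector of the five file paths.
#' @export
make_fixtures <- function(output_dir) {
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  paths <- vapply(names(solvent_shift_table), function(nm) {
    p <- file.path(output_dir, paste0(nm, ".peaks"))
    write_peak_list(solvent_shift_table[[nm]], unit = "ppm", path = p,
                    comment = paste0(nm, " 13C chemical shifts"))
    p
  }, character(1))
  invisible(paths)
}
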