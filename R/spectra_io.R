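#' Single absorption spectrum
#'
#' Container for one UV-Vis absorption spectrum: a strictly increasing
#' wavelength axis in nm and absorbance in AU.
#'
#' @param wavelength Numeric vector of wavelengths (nm), strictly increasing,
#'   non-negative.
#' @param absorbance Numeric vector of absorbances (AU), same length.
#' @param label Free-text label (e.g. the source file name).
#' @return An object of class `dye_spectrum`.
#' @export
dye_spectrum <- function(wavelength, absorbance, label = "") {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    stopf("wavelength (%d) and absorbance (%d) differ in length%s",
          length(wavelength), length(absorbance),
          if (nzchar(label)) paste0(" in ", label) else "")
  if (any(wavelength < 0))
    stopf("negative wavelengths%s", if (nzchar(label)) paste0(" in ", label) else "")
  if (any(diff(wavelength) <= 0))
    stopf("wavelength axis is not strictly increasing%s",
          if (nzchar(label)) paste0(" in '", label, "'") else "")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 label = as.character(label)),
            class = "dye_spectrum")
}

#' @export
print.dye_spectrum <- function(x, ...) {
  cat(sprintf("<dye_spectrum%s: %d points, %g-%g nm>\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Band integration window
#'
#' @param lambda_lo,lambda_hi Window bounds in nm, `lambda_lo < lambda_hi`.
#' @return An object of class `band_window`.
#' @export
band_window <- function(lambda_lo, lambda_hi) {
  if (!is.numeric(lambda_lo) || !is.numeric(lambda_hi) ||
      length(lambda_lo) != 1 || length(lambda_hi) != 1)
    stopf("band window bounds must be single numbers")
  if (lambda_lo >= lambda_hi)
    stopf("band window requires lambda_lo < lambda_hi (got [%g, %g])",
          lambda_lo, lambda_hi)
  structure(list(lambda_lo = as.numeric(lambda_lo),
                 lambda_hi = as.numeric(lambda_hi)),
            class = "band_window")
}

#' Concentration series of spectra
#'
#' Bundles spectra with their total dye concentrations and the cuvette path
#' length. Spectra are re-sorted by ascending concentration; spectra on a
#' different wavelength grid than the first are linearly interpolated onto
#' the first spectrum's grid (with a message).
#'
#' @param spectra List of [dye_spectrum()] objects.
#' @param concentrations Total dye concentrations in mol/L, one per spectrum,
#'   all positive.
#' @param path_length Optical path length in cm (default 1).
#' @return An object of class `spectral_series`.
#' @export
spectral_series <- function(spectra, concentrations, path_length = 1) {
  if (!is.list(spectra) || !all(vapply(spectra, inherits, TRUE, "dye_spectrum")))
    stopf("'spectra' must be a list of dye_spectrum objects")
  concentrations <- as.numeric(concentrations)
  if (length(spectra) != length(concentrations))
    stopf("got %d spectra but %d concentrations",
          length(spectra), length(concentrations))
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stopf("concentrations must all be positive and finite")
  if (!is.numeric(path_length) || length(path_length) != 1 || path_length <= 0)
    stopf("path_length must be a single positive number (cm)")

  grid <- spectra[[1]]$wavelength
  regridded <- FALSE
  spectra <- lapply(spectra, function(sp) {
    if (length(sp$wavelength) == length(grid) &&
        isTRUE(all.equal(sp$wavelength, grid))) return(sp)
    regridded <<- TRUE
    ab <- stats::approx(sp$wavelength, sp$absorbance, xout = grid, rule = 1)$y
    if (anyNA(ab))
      stopf("spectrum '%s' does not cover the common wavelength grid", sp$label)
    dye_spectrum(grid, ab, sp$label)
  })
  if (regridded)
    message("spectra interpolated onto the first spectrum's wavelength grid")

  o <- order(concentrations)
  structure(list(spectra = spectra[o], concentrations = concentrations[o],
                 path_length = as.numeric(path_length)),
            class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf("<spectral_series: %d spectra, C %.3g-%.3g M, path %g cm>\n",
              length(x$spectra), min(x$concentrations), max(x$concentrations),
              x$path_length))
  invisible(x)
}

## Read a delimited numeric table, '#' comments ignored, delimiter
## auto-detected (tab, comma, or whitespace). Returns the numeric matrix and
## the header tokens if the first line is non-numeric.
read_delim_auto <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stopf("file '%s' has no data", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else if (grepl(",", lines[[1]])) "," else ""
  split1 <- strsplit(trimws(lines[[1]]), if (sep == "") "\\s+" else sep)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(split1[[1]])))
  dat <- utils::read.table(text = paste(lines[if (has_header) -1L else TRUE],
                                        collapse = "\n"),
                           sep = sep, header = FALSE,
                           colClasses = "numeric")
  list(data = as.matrix(dat), header = if (has_header) split1 else NULL)
}

#' Read a spectral series from delimited text files
#'
#' Accepts either one *wide* file (column 1 = wavelength in nm, remaining
#' columns = absorbance at each concentration, with a header line
#' `wavelength,<C1>,<C2>,...` carrying the concentrations in mol/L) or
#' several two-column files, one per concentration, with the concentrations
#' supplied through `concentrations`. Comma, tab or whitespace delimiters
#' are auto-detected and `#`-prefixed lines are ignored.
#'
#' @param paths Character vector of file paths.
#' @param concentrations Concentrations in mol/L, one per file (or one per
#'   wide column when the wide file has no concentration header).
#' @param path_length Cuvette path length in cm.
#' @return A [spectral_series()].
#' @export
read_spectra_series <- function(paths, concentrations = NULL, path_length = 1) {
  if (length(paths) < 1) stopf("no input files given")
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stopf("input file not found: %s", paste(missing_files, collapse = ", "))

  if (length(paths) == 1) {
    tab <- read_delim_auto(paths)
    if (ncol(tab$data) > 2) {
      conc <- concentrations
      if (is.null(conc) && !is.null(tab$header)) {
        conc <- suppressWarnings(as.numeric(tab$header[-1]))
        if (anyNA(conc))
          stopf("wide file '%s' header does not carry numeric concentrations",
                paths)
      }
      if (is.null(conc))
        stopf("wide file '%s' needs a concentration header or 'concentrations'",
              paths)
      if (length(conc) != ncol(tab$data) - 1)
        stopf("wide file '%s': %d absorbance columns but %d concentrations",
              paths, ncol(tab$data) - 1, length(conc))
      wl <- tab$data[, 1]
      if (any(diff(wl) <= 0))
        stopf("wavelength axis is not strictly increasing in '%s'", paths)
      spectra <- lapply(seq_along(conc), function(j)
        dye_spectrum(wl, tab$data[, j + 1], label = sprintf("%s[%d]", paths, j)))
      return(spectral_series(spectra, conc, path_length))
    }
    ## fall through: single two-column file
  }

  if (is.null(concentrations))
    stopf("per-file input requires 'concentrations'")
  if (length(paths) != length(concentrations))
    stopf("got %d files but %d concentrations",
          length(paths), length(concentrations))
  spectra <- lapply(paths, function(p) {
    tab <- read_delim_auto(p)
    if (ncol(tab$data) != 2)
      stopf("file '%s' is not a two-column spectrum", p)
    if (any(diff(tab$data[, 1]) <= 0))
      stopf("wavelength axis is not strictly increasing in '%s'", p)
    dye_spectrum(tab$data[, 1], tab$data[, 2], label = p)
  })
  spectral_series(spectra, concentrations, path_length)
}

#' Write a spectral series as one wide delimited file
#'
#' Column 1 is the wavelength (nm); the header carries the concentrations in
#' mol/L, so the file round-trips through [read_spectra_series()].
#'
#' @param series A [spectral_series()].
#' @param path Output file path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra_series <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "spectral_series"))
  wl <- series$spectra[[1]]$wavelength
  mat <- cbind(wl, sapply(series$spectra, `[[`, "absorbance"))
  header <- paste(c("wavelength", format(series$concentrations, digits = 15)),
                  collapse = sep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# path_length_cm %g", series$path_length), header), con)
  utils::write.table(mat, con, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Integral absorbance over a band window
#'
#' Trapezoidal area of absorbance over `[lambda_lo, lambda_hi]` on the
#' recorded grid. Window endpoints falling between grid points are included
#' by linear interpolation. Exact for piecewise-linear spectra.
#'
#' @param spectrum A [dye_spectrum()].
#' @param window A [band_window()]; must lie inside the spectrum's range.
#' @return Integral absorbance in AU nm.
#' @export
integrate_band <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "dye_spectrum"), inherits(window, "band_window"))
  wl <- spectrum$wavelength
  if (window$lambda_lo < wl[1] || window$lambda_hi > wl[length(wl)])
    stopf("window [%g, %g] outside the wavelength grid [%g, %g]",
          window$lambda_lo, window$lambda_hi, wl[1], wl[length(wl)])
  inner <- wl > window$lambda_lo & wl < window$lambda_hi
  x <- c(window$lambda_lo, wl[inner], window$lambda_hi)
  y <- c(stats::approx(wl, spectrum$absorbance, window$lambda_lo)$y,
         spectrum$absorbance[inner],
         stats::approx(wl, spectrum$absorbance, window$lambda_hi)$y)
  pracma::trapz(x, y)
}

#' Absorbance curve: integral absorbance vs concentration
#'
#' The reduced form of a spectral series: one integral absorbance per total
#' concentration. This is the input to the aggregation fit.
#'
#' @param concentrations Total concentrations in mol/L, strictly increasing
#'   after sorting (duplicates are rejected).
#' @param integral_absorbance Integral absorbances in AU nm, same length.
#' @param path_length Path length in cm.
#' @param window Optional [band_window()] used for the integration.
#' @return An object of class `absorbance_curve`.
#' @export
absorbance_curve <- function(concentrations, integral_absorbance,
                             path_length = 1, window = NULL) {
  concentrations <- as.numeric(concentrations)
  integral_absorbance <- as.numeric(integral_absorbance)
  if (length(concentrations) != length(integral_absorbance))
    stopf("concentrations (%d) and integral_absorbance (%d) differ in length",
          length(concentrations), length(integral_absorbance))
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stopf("concentrations must be positive and finite")
  o <- order(concentrations)
  concentrations <- concentrations[o]
  integral_absorbance <- integral_absorbance[o]
  if (any(diff(concentrations) <= 0))
    stopf("concentrations must be strictly increasing (duplicates present)")
  structure(list(concentrations = concentrations,
                 integral_absorbance = integral_absorbance,
                 path_length = as.numeric(path_length),
                 window = window),
            class = "absorbance_curve")
}

#' @export
print.absorbance_curve <- function(x, ...) {
  cat(sprintf("<absorbance_curve: %d points, C %.3g-%.3g M>\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations)))
  invisible(x)
}

#' Reduce a spectral series to an absorbance curve
#'
#' @param series A [spectral_series()].
#' @param window A [band_window()].
#' @return An [absorbance_curve()] with one point per concentration.
#' @export
to_absorbance_curve <- function(series, window) {
  stopifnot(inherits(series, "spectral_series"))
  a <- vapply(series$spectra, integrate_band, numeric(1), window = window)
  absorbance_curve(series$concentrations, a, series$path_length, window)
}

#' Write / read an absorbance curve as two-column delimited text
#'
#' Format: header `concentration_M,integral_absorbance_AU_nm`, one row per
#' point; `#` comment lines carry the path length.
#'
#' @param curve An [absorbance_curve()].
#' @param path File path.
#' @return `path` invisibly (write); an [absorbance_curve()] (read).
#' @export
write_absorbance_curve <- function(curve, path) {
  stopifnot(inherits(curve, "absorbance_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# path_length_cm %g", curve$path_length), con)
  if (!is.null(curve$window))
    writeLines(sprintf("# window_nm %g %g", curve$window$lambda_lo,
                       curve$window$lambda_hi), con)
  writeLines("concentration_M,integral_absorbance_AU_nm", con)
  utils::write.table(cbind(curve$concentrations, curve$integral_absorbance),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_absorbance_curve
#' @export
read_absorbance_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pl <- 1
  m <- regmatches(lines, regexec("^#\\s*path_length_cm\\s+(\\S+)", lines))
  hit <- which(lengths(m) == 2)
  if (length(hit)) pl <- as.numeric(m[[hit[1]]][2])
  tab <- read_delim_auto(path)
  absorbance_curve(tab$data[, 1], tab$data[, 2], path_length = pl)
}
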