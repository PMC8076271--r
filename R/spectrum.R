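#' Construct an Amide I spectrum
#'
#' @param wavenumbers strictly increasing wavenumber grid (cm^-1).
#' @param absorbance absorbance trace (a.u.), same length, no NaN.
#' @param mode acquisition mode: "atr_ftir", "ir_microscopy" or "synthetic".
#' @return an `amide_spectrum` list with fields `wavenumbers`, `absorbance`,
#'   `mode`.
#' @export
new_spectrum <- function(wavenumbers, absorbance,
                         mode = c("atr_ftir", "ir_microscopy", "synthetic")) {
  mode <- match.arg(mode)
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumber and absorbance arrays differ in length")
  }
  if (any(!is.finite(wavenumbers)) || any(!is.finite(absorbance))) {
    stop("spectrum contains non-finite values")
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing (storage order is fixed)")
  }
  if (sum(wavenumbers >= 1580 & wavenumbers <= 1720) < 50) {
    stop("need at least 50 points across the 1580-1720 cm^-1 analysis window")
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 mode = mode), class = "amide_spectrum")
}

#' @export
print.amide_spectrum <- function(x, ...) {
  cat(sprintf("<amide_spectrum> %d points, %.0f-%.0f cm^-1, mode %s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$mode))
  invisible(x)
}

#' Read a spectrum from two-column delimited text
#'
#' Accepts whitespace- or comma-delimited text with one `wavenumber
#' absorbance` pair per line; `#` starts a comment. Rows are sorted into
#' ascending wavenumber order.
#'
#' @param path input file.
#' @param mode acquisition mode tag, see [new_spectrum()].
#' @return an `amide_spectrum`.
#' @export
read_spectrum <- function(path, mode = "atr_ftir") {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[,;[:space:]]+")
  if (!all(lengths(parts) == 2)) {
    stop("expected two columns (wavenumber, absorbance) in ", path)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2,
                byrow = TRUE)
  if (anyNA(mat)) {
    stop("non-numeric spectral data in ", path)
  }
  ord <- order(mat[, 1])
  new_spectrum(mat[ord, 1], mat[ord, 2], mode = mode)
}

#' Average several spectra point-wise
#'
#' The only supported reduction of a spectral map: the arithmetic mean trace
#' over spectra sharing one wavenumber grid.
#'
#' @param spectra list of `amide_spectrum` objects on a common grid.
#' @return an `amide_spectrum` holding the mean trace.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, logical(1), "amide_spectrum")))
  grid <- spectra[[1]]$wavenumbers
  for (sp in spectra) {
    if (!isTRUE(all.equal(sp$wavenumbers, grid))) {
      stop("spectra are not on a common wavenumber grid")
    }
  }
  traces <- vapply(spectra, `[[`, numeric(length(grid)), "absorbance")
  new_spectrum(grid, rowMeans(traces), mode = spectra[[1]]$mode)
}
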