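#' Construct a spectrum on the canonical grid
#'
#' A spectrum is a wavelength-tabulated function on the canonical 400-700 nm,
#' 10 nm grid: spectral power per band for illuminants and LED channels, or a
#' unitless reflectance in \[0, 1\].
#'
#' @param values numeric vector, one value per grid wavelength.
#' @param role one of "illuminant", "reflectance", "channel".
#' @param wavelengths wavelength grid in nm; must equal [canonical_grid()].
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(values, role = c("illuminant", "reflectance", "channel"),
                     wavelengths = canonical_grid()) {
  role <- match.arg(role)
  grid <- canonical_grid()
  if (length(wavelengths) != length(grid) || any(wavelengths != grid)) {
    stop("spectrum grid must be the canonical 400-700 nm / 10 nm grid (",
         "got ", length(wavelengths), " samples from ", min(wavelengths),
         " to ", max(wavelengths), " nm)")
  }
  values <- as.numeric(values)
  if (length(values) != length(grid)) {
    stop("expected ", length(grid), " spectral values, got ", length(values))
  }
  if (any(!is.finite(values))) stop("spectral values must be finite")
  neg <- values < 0
  if (any(neg)) {
    worst <- max(-values[neg]) / max(max(abs(values)), .Machine$double.eps)
    if (worst > 1e-6) {
      warning("clipping negative spectral values (largest relative magnitude ",
              signif(worst, 3), ") to 0")
    }
    values[neg] <- 0
  }
  if (role == "reflectance" && any(values > 1)) {
    stop("reflectance values must lie in [0, 1]")
  }
  structure(list(wavelengths = grid, values = values, role = role),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> role:", x$role,
      sprintf("| %d bands %g-%g nm | range [%.4g, %.4g]\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

# Ensure two spectra share one grid before a binary operation.
check_same_grid <- function(a, b) {
  if (!identical(a$wavelengths, b$wavelengths)) {
    stop("spectra are on different grids: ",
         paste(range(a$wavelengths), collapse = "-"), " nm vs ",
         paste(range(b$wavelengths), collapse = "-"), " nm")
  }
  invisible(TRUE)
}

#' Resample a tabulated spectral function to the canonical grid
#'
#' Linear interpolation; wavelengths outside the tabulated support are set
#' to 0.
#'
#' @param wavelengths,values tabulated function.
#' @param role spectrum role for the result.
#' @return A [spectrum()].
#' @export
resample_spectrum <- function(wavelengths, values, role = "illuminant") {
  grid <- canonical_grid()
  v <- stats::approx(wavelengths, values, xout = grid, rule = 1)$y
  v[is.na(v)] <- 0
  spectrum(v, role = role)
}

#' Read a spectrum from a two-column CSV
#'
#' Expected columns: `wavelength_nm`, `value`, with a one-line header. The
#' tabulation is resampled to the canonical grid.
#'
#' @param path file path.
#' @param role spectrum role.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, role = "illuminant") {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    stop("spectrum CSV must have columns wavelength_nm, value: ", path)
  }
  resample_spectrum(d$wavelength_nm, d$value, role = role)
}

#' Write a spectrum to a two-column CSV
#'
#' @param s a [spectrum()].
#' @param path file path.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(is_spectrum(s))
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelengths, value = s$values),
    path, row.names = FALSE)
  invisible(path)
}
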