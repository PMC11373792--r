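# Band-index <-> wavelength calibration for line-scan hyperspectral imagers.
# Band indices are 1-based throughout the package.

# The six published (band, nm) window endpoints of the benchtop imager:
# red 173-292 = 620.05-779.75 nm, green 76-127 = 491.19-558.79 nm,
# blue 23-44 = 421.29-448.94 nm.
.window_endpoints <- data.frame(
  band = c(23L, 44L, 76L, 127L, 173L, 292L),
  nm   = c(421.29, 448.94, 491.19, 558.79, 620.05, 779.75)
)

#' Wavelength calibration
#'
#' Describes how 1-based band indices map to wavelengths in nanometres,
#' either as an explicit per-band list or as a linear model
#' `lambda(b) = offset_nm + step_nm * b`.
#'
#' @param wavelengths_nm Numeric vector of per-band wavelengths (explicit
#'   mode). Must be strictly increasing.
#' @param offset_nm,step_nm Linear-model parameters (linear mode);
#'   `step_nm` must be positive.
#' @param n_bands Number of calibrated bands.
#' @return An object of class `wavelength_calibration`.
#' @export
wavelength_calibration <- function(wavelengths_nm = NULL, offset_nm = NULL,
                                   step_nm = NULL, n_bands = NULL) {
  if (!is.null(wavelengths_nm)) {
    wavelengths_nm <- as.numeric(wavelengths_nm)
    if (length(wavelengths_nm) < 1L)
      stop("explicit calibration needs at least one wavelength")
    if (any(diff(wavelengths_nm) <= 0))
      stop("wavelengths must be strictly increasing with band index")
    cal <- list(mode = "explicit", wavelengths_nm = wavelengths_nm,
                n_bands = length(wavelengths_nm))
  } else {
    if (is.null(offset_nm) || is.null(step_nm) || is.null(n_bands))
      stop("linear calibration needs offset_nm, step_nm and n_bands")
    if (step_nm <= 0) stop("step_nm must be > 0")
    cal <- list(mode = "linear", offset_nm = as.numeric(offset_nm),
                step_nm = as.numeric(step_nm), n_bands = as.integer(n_bands))
  }
  class(cal) <- "wavelength_calibration"
  cal
}

#' Default imager calibration
#'
#' Least-squares line through the six published window endpoints of the
#' 462-band, 400-1000 nm benchtop imager. All endpoints are reproduced
#' with residual under 1.5 nm (one band step).
#'
#' @param n_bands Number of bands (default 462).
#' @return A linear `wavelength_calibration`.
#' @export
default_calibration <- function(n_bands = 462L) {
  fit <- stats::lm.fit(cbind(1, .window_endpoints$band), .window_endpoints$nm)
  wavelength_calibration(offset_nm = fit$coefficients[1],
                         step_nm = fit$coefficients[2],
                         n_bands = n_bands)
}

#' @export
print.wavelength_calibration <- function(x, ...) {
  if (x$mode == "linear")
    cat(sprintf("wavelength_calibration: linear, %d bands, lambda(b) = %.3f + %.5f b nm\n",
                x$n_bands, x$offset_nm, x$step_nm))
  else
    cat(sprintf("wavelength_calibration: explicit, %d bands, %.2f-%.2f nm\n",
                x$n_bands, x$wavelengths_nm[1], x$wavelengths_nm[x$n_bands]))
  invisible(x)
}

#' Wavelength of a band
#'
#' @param cal A `wavelength_calibration`.
#' @param band 1-based band index (vectorised).
#' @return Wavelength(s) in nm.
#' @export
wavelength_of_band <- function(cal, band) {
  stopifnot(inherits(cal, "wavelength_calibration"))
  band <- as.integer(band)
  if (any(band < 1L) || any(band > cal$n_bands))
    stop(sprintf("band out of calibrated range 1..%d", cal$n_bands))
  if (cal$mode == "linear") cal$offset_nm + cal$step_nm * band
  else cal$wavelengths_nm[band]
}

#' Nearest band for a wavelength
#'
#' Inverse of [wavelength_of_band()]: returns the band whose calibrated
#' wavelength is closest to `nm` (ties towards the lower band).
#'
#' @param cal A `wavelength_calibration`.
#' @param nm Wavelength(s) in nanometres.
#' @return 1-based band index/indices.
#' @export
band_of_wavelength <- function(cal, nm) {
  stopifnot(inherits(cal, "wavelength_calibration"))
  all_nm <- wavelength_of_band(cal, seq_len(cal$n_bands))
  vapply(as.numeric(nm), function(w) which.min(abs(all_nm - w)), integer(1))
}
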