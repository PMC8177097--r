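#' Construct a spectrum
#'
#' A wavelength-indexed trace (absorbance in AU or emission in counts) on a
#' strictly increasing wavelength grid.
#'
#' @param wavelength Wavelengths in nm, strictly increasing.
#' @param values Observable values, same length.
#' @return A `spectrum` object.
#' @export
spectrum <- function(wavelength, values) {
  if (length(wavelength) != length(values))
    stop("'wavelength' and 'values' lengths differ", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0))
    stop("'wavelength' must be finite and strictly increasing", call. = FALSE)
  structure(list(wavelength = wavelength, values = values),
            class = "spectrum")
}

#' Differential spectrum (sample minus reference)
#'
#' Point-wise subtraction of a reference read (e.g. the same amount of free
#' ligand in buffer) from a sample read, isolating the bound-complex signal.
#' The two spectra must share the wavelength grid exactly; no interpolation
#' is performed.
#'
#' @param sample,reference `spectrum` objects on identical grids.
#' @return A `spectrum` holding `sample - reference`.
#' @export
differential_spectrum <- function(sample, reference) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  if (length(sample$wavelength) != length(reference$wavelength) ||
      any(sample$wavelength != reference$wavelength))
    stop("wavelength grids differ; refusing to interpolate", call. = FALSE)
  spectrum(sample$wavelength, sample$values - reference$values)
}

#' Locate the Soret peak in a spectrum
#'
#' Finds the wavelength of maximum signal within a search window. The
#' discrete argmax is refined by fitting a quadratic through it and its two
#' neighbours; a window whose maximum sits on the window edge (monotone
#' signal) yields a no-peak result rather than a spurious boundary value.
#'
#' @param spec A `spectrum`.
#' @param window Two-element nm interval to search (default `c(400, 430)`,
#'   the porphyrin Soret region).
#' @return A list with `found` (logical), `wavelength` (nm, `NA` if not
#'   found) and `value` (interpolated height).
#' @export
find_soret_peak <- function(spec, window = c(400, 430)) {
  stopifnot(inherits(spec, "spectrum"), length(window) == 2L)
  if (window[1] < min(spec$wavelength) || window[2] > max(spec$wavelength))
    stop("search window outside the spectrum range", call. = FALSE)
  sel <- which(spec$wavelength >= window[1] & spec$wavelength <= window[2])
  if (length(sel) < 3L)
    stop("fewer than 3 points in the search window", call. = FALSE)
  w <- spec$wavelength[sel]; v <- spec$values[sel]
  i <- which.max(v)
  if (i == 1L || i == length(v))
    return(list(found = FALSE, wavelength = NA_real_, value = NA_real_))
  # quadratic through the argmax and both neighbours
  x <- w[(i - 1):(i + 1)]; y <- v[(i - 1):(i + 1)]
  co <- stats::lm.fit(cbind(1, x, x^2), y)$coefficients
  if (!is.finite(co[3]) || co[3] >= 0)
    return(list(found = TRUE, wavelength = w[i], value = v[i]))
  xv <- -co[2] / (2 * co[3])
  list(found = TRUE, wavelength = unname(xv),
       value = unname(co[1] + co[2] * xv + co[3] * xv^2))
}
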