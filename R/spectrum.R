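#' Spectrum container for a single channel
#'
#' One spectrum on a strictly increasing wavelength grid within 640-850 nm.
#' Fluorescence channels (`ChlF_UP`, `ChlF_DOWN`) and reflected/transmitted
#' radiance (`Rad_UP`, `Rad_DOWN`) are directional radiances in
#' mW m-2 nm-1 sr-1; `ChlF_PS` is a hemispheric spectral flux in mW m-2 nm-1
#' (the Lambertian pi factor has already been applied).
#'
#' @param wavelengths numeric, strictly increasing grid in nm.
#' @param values numeric radiances; `NA` marks masked wavelengths.
#' @param channel one of `"ChlF_UP"`, `"ChlF_DOWN"`, `"Rad_UP"`, `"Rad_DOWN"`,
#'   `"ChlF_PS"`.
#' @return A `spectrum_sample` object (list with `wavelengths`, `values`,
#'   `channel`).
#' @export
spectrum_sample <- function(wavelengths, values,
                            channel = c("ChlF_UP", "ChlF_DOWN", "Rad_UP",
                                        "Rad_DOWN", "ChlF_PS")) {
  channel <- match.arg(channel)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop_fluoql("wavelength grid (%d) and values (%d) differ in length",
                length(wavelengths), length(values))
  if (any(diff(wavelengths) <= 0))
    stop_fluoql("wavelength grid must be strictly increasing")
  if (any(values < 0, na.rm = TRUE) && channel != "ChlF_PS")
    stop_fluoql("negative radiance in channel %s", channel)
  structure(list(wavelengths = wavelengths, values = values,
                 channel = channel),
            class = "spectrum_sample")
}

#' @export
print.spectrum_sample <- function(x, ...) {
  cat(sprintf("<spectrum_sample> %s: %d wavelengths, %.1f-%.1f nm\n",
              x$channel, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Leaf optical properties on a wavelength grid
#'
#' @param wavelengths numeric grid, nm.
#' @param rho,tau reflectance and transmittance, each in \[0, 1) with
#'   `rho + tau < 1` elementwise.
#' @return A `leaf_optics` object.
#' @export
leaf_optics <- function(wavelengths, rho, tau) {
  wavelengths <- as.numeric(wavelengths)
  stopifnot(length(rho) == length(wavelengths),
            length(tau) == length(wavelengths))
  if (any(rho < 0) || any(tau < 0) || any(rho + tau >= 1))
    stop_fluoql("leaf optics require 0 <= rho, tau and rho + tau < 1")
  structure(list(wavelengths = wavelengths, rho = as.numeric(rho),
                 tau = as.numeric(tau)),
            class = "leaf_optics")
}

#' Elementary PSII and PSI emission basis
#'
#' Shape functions (spectral densities, nm-1) for the two photosystems on a
#' common grid, each normalized to unit integral over the grid so that
#' mixture coefficients carry the full-band energy flux.
#'
#' @param wavelengths numeric grid, nm.
#' @param s_psii,s_psi non-negative spectral densities; renormalized to unit
#'   trapezoidal integral.
#' @return An `emission_basis` object.
#' @export
emission_basis <- function(wavelengths, s_psii, s_psi) {
  wavelengths <- as.numeric(wavelengths)
  stopifnot(length(s_psii) == length(wavelengths),
            length(s_psi) == length(wavelengths))
  if (any(s_psii < 0) || any(s_psi < 0))
    stop_fluoql("emission basis densities must be non-negative")
  s_psii <- s_psii / trapz(wavelengths, s_psii)
  s_psi <- s_psi / trapz(wavelengths, s_psi)
  structure(list(wavelengths = wavelengths, s_psii = s_psii, s_psi = s_psi),
            class = "emission_basis")
}

# Linear interpolation of a per-wavelength quantity onto a target grid.
# Errors if the target extends beyond the source by more than `tol` nm.
interp_to_grid <- function(x_src, y_src, x_out, tol = 1, what = "spectrum") {
  if (min(x_out) < min(x_src) - tol || max(x_out) > max(x_src) + tol)
    stop_fluoql("%s grid (%.1f-%.1f nm) does not cover target (%.1f-%.1f nm)",
                what, min(x_src), max(x_src), min(x_out), max(x_out))
  approx(x_src, y_src, xout = x_out, rule = 2)$y
}
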