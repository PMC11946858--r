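#' Photosystem-level fluorescence from bidirectional leaf emission
#'
#' Leaf-emitted fluorescence is attenuated by within-leaf reabsorption
#' (strongly so near the 686 nm red peak). The photosystem-level spectrum is
#' recovered by scaling the total escaping emission by the escape
#' probability `rho + tau` and converting radiance to hemispheric flux with
#' the Lambertian factor pi:
#' `ChlF_PS = (ChlF_UP + ChlF_DOWN) / (rho + tau) * pi`.
#' Wavelengths where `rho + tau` falls below `escape_floor` are masked to
#' avoid amplifying noise in the strong-absorption region.
#'
#' @param chlf_up,chlf_down [spectrum_sample()] objects (mW m-2 nm-1 sr-1).
#' @param optics a [leaf_optics()] object.
#' @param escape_floor minimum `rho + tau` retained (default 0.02).
#' @param grid_tol grid harmonization tolerance, nm.
#' @return A [spectrum_sample()] with channel `ChlF_PS` (mW m-2 nm-1).
#' @export
photosystem_fluorescence <- function(chlf_up, chlf_down, optics,
                                     escape_floor = 0.02, grid_tol = 1) {
  stopifnot(inherits(chlf_up, "spectrum_sample"),
            inherits(chlf_down, "spectrum_sample"),
            inherits(optics, "leaf_optics"))
  wl <- chlf_up$wavelengths
  down <- interp_to_grid(chlf_down$wavelengths, chlf_down$values, wl,
                         tol = grid_tol, what = "ChlF_DOWN")
  rho <- interp_to_grid(optics$wavelengths, optics$rho, wl,
                        tol = grid_tol, what = "leaf optics")
  tau <- interp_to_grid(optics$wavelengths, optics$tau, wl,
                        tol = grid_tol, what = "leaf optics")
  escape <- rho + tau
  values <- (chlf_up$values + down) / escape * pi
  values[escape < escape_floor] <- NA_real_
  spectrum_sample(wl, values, channel = "ChlF_PS")
}

# Two-column non-negative least squares by closed-form active set:
# try the unconstrained normal-equation solution; if a coefficient is
# negative, refit each single-column model with the other clamped at zero
# and keep the lower-SSE candidate.
nnls2 <- function(a1, a2, y) {
  g11 <- sum(a1 * a1); g22 <- sum(a2 * a2); g12 <- sum(a1 * a2)
  det_g <- g11 * g22 - g12^2
  if (det_g < 1e-10 * g11 * g22)
    stop_fluoql("emission basis is ill-conditioned (near-collinear components)")
  b1 <- sum(a1 * y); b2 <- sum(a2 * y)
  c1 <- (g22 * b1 - g12 * b2) / det_g
  c2 <- (g11 * b2 - g12 * b1) / det_g
  if (c1 >= 0 && c2 >= 0) return(c(c1, c2))
  cand <- list(c(max(b1 / g11, 0), 0), c(0, max(b2 / g22, 0)))
  sse <- vapply(cand, function(cc)
    sum((y - cc[1] * a1 - cc[2] * a2)^2), numeric(1))
  cand[[which.min(sse)]]
}

#' Partition photosystem fluorescence into PSII and PSI components
#'
#' Solves `min || ChlF_PS - c_psii * s_psii - c_psi * s_psi ||^2` subject to
#' non-negative coefficients on the common grid, then forms the
#' per-wavelength PSII contribution
#' `f_PSII(lambda) = c_psii * s_psii / (c_psii * s_psii + c_psi * s_psi)`.
#'
#' @param chlf_ps a `ChlF_PS` [spectrum_sample()]; must cover at least the
#'   660-800 nm core of the basis support.
#' @param basis an [emission_basis()].
#' @param grid_tol grid harmonization tolerance, nm.
#' @return A `ps_decomposition` object: `c_psii`, `c_psi` (mW m-2),
#'   `wavelengths`, `f_psii_by_lambda`, `residual_norm` (relative).
#' @export
decompose_psii_psi <- function(chlf_ps, basis, grid_tol = 1) {
  stopifnot(inherits(chlf_ps, "spectrum_sample"),
            inherits(basis, "emission_basis"))
  if (chlf_ps$channel != "ChlF_PS")
    stop_fluoql("decomposition expects a ChlF_PS spectrum, got %s",
                chlf_ps$channel)
  keep <- is.finite(chlf_ps$values)
  wl <- chlf_ps$wavelengths[keep]
  y <- chlf_ps$values[keep]
  if (length(wl) < 10 || min(wl) > 660 || max(wl) < 800)
    stop_fluoql("ChlF_PS must cover the 660-800 nm core of the emission basis")
  if (all(y == 0))
    stop_fluoql("all-zero ChlF_PS spectrum cannot be decomposed")
  s2 <- interp_to_grid(basis$wavelengths, basis$s_psii, wl,
                       tol = grid_tol, what = "PSII basis")
  s1 <- interp_to_grid(basis$wavelengths, basis$s_psi, wl,
                       tol = grid_tol, what = "PSI basis")
  cc <- nnls2(s2, s1, y)
  fit2 <- cc[1] * s2
  fit1 <- cc[2] * s1
  total <- fit2 + fit1
  f_psii <- ifelse(total > 0, fit2 / total, NA_real_)
  resid <- y - total
  structure(list(c_psii = cc[1], c_psi = cc[2], wavelengths = wl,
                 f_psii_by_lambda = f_psii,
                 residual_norm = sqrt(sum(resid^2) / sum(y^2))),
            class = "ps_decomposition")
}

#' PSII contribution at a wavelength
#'
#' Interpolates `f_psii_by_lambda` from a decomposition at the requested
#' wavelength; the O2-A band 760 nm and the Fraunhofer-line 740 nm are the
#' usual choices.
#'
#' @param decomp a `ps_decomposition` from [decompose_psii_psi()].
#' @param lambda_nm wavelength, nm, within the decomposition grid.
#' @return f_PSII in \[0, 1\].
#' @export
f_psii_at <- function(decomp, lambda_nm) {
  stopifnot(inherits(decomp, "ps_decomposition"))
  rng <- range(decomp$wavelengths)
  if (any(lambda_nm < rng[1]) || any(lambda_nm > rng[2]))
    stop_fluoql("lambda %g nm outside the decomposition grid (%.1f-%.1f nm)",
                lambda_nm[1], rng[1], rng[2])
  approx(decomp$wavelengths, decomp$f_psii_by_lambda, xout = lambda_nm)$y
}

#' Energy to photon flux density
#'
#' Converts spectral energy flux (mW m-2 nm-1) at wavelength lambda to
#' photon flux density (umol photons m-2 s-1 nm-1) via `E = h c / lambda`.
#'
#' @param value spectral energy flux, mW m-2 nm-1.
#' @param lambda_nm wavelength, nm, > 0.
#' @return photon flux density, umol m-2 s-1 nm-1.
#' @export
energy_to_photon_flux <- function(value, lambda_nm) {
  if (any(lambda_nm <= 0)) stop_fluoql("wavelength must be positive")
  value * 1e-3 * lambda_nm * 1e-9 / (PLANCK_H * LIGHT_C) / AVOGADRO * 1e6
}

#' Spectral-to-broadband conversion factor f_C
#'
#' Translates the PSII spectral fluorescence at a single wavelength into
#' full-band PSII photon flux using the elementary PSII emission shape:
#' `f_C(lambda) = integral(photon_flux(s_psii)) / photon_flux(s_psii(lambda))`
#' (units nm). Scale-invariant in the basis amplitude; trapezoidal
#' integration on the native basis grid.
#'
#' @param basis an [emission_basis()].
#' @param lambda_nm evaluation wavelength, nm; `s_psii(lambda)` must be > 0.
#' @return f_C in nm.
#' @export
conversion_factor_fc <- function(basis, lambda_nm) {
  stopifnot(inherits(basis, "emission_basis"))
  wl <- basis$wavelengths
  if (lambda_nm < min(wl) || lambda_nm > max(wl))
    stop_fluoql("lambda %g nm outside the basis support", lambda_nm)
  pf <- energy_to_photon_flux(basis$s_psii, wl)
  pf_at <- approx(wl, pf, xout = lambda_nm)$y
  if (!is.finite(pf_at) || pf_at <= 0)
    stop_fluoql("PSII basis vanishes at %g nm; f_C undefined there", lambda_nm)
  trapz(wl, pf) / pf_at
}

#' Broadband PSII fluorescence from a passive spectrum
#'
#' The headline passive estimate: photosystem-level fluorescence at one
#' wavelength, scaled by the PSII contribution and the spectral-to-broadband
#' conversion factor, in photon units:
#' `ChlF_PSII = photon_flux(ChlF_PS(lambda)) * f_PSII(lambda) * f_C(lambda)`.
#' For spectra exactly composed from the basis the result is independent of
#' the chosen wavelength.
#'
#' @param chlf_ps a `ChlF_PS` [spectrum_sample()] (mW m-2 nm-1).
#' @param decomp matching `ps_decomposition`.
#' @param basis the [emission_basis()] used for the decomposition.
#' @param lambda_nm retrieval wavelength; 760 (O2-A) or 740 nm typical.
#' @return ChlF_PSII in umol m-2 s-1.
#' @export
chlf_psii_from_passive <- function(chlf_ps, decomp, basis, lambda_nm = 760) {
  stopifnot(inherits(chlf_ps, "spectrum_sample"))
  ps_at <- approx(chlf_ps$wavelengths, chlf_ps$values, xout = lambda_nm)$y
  if (!is.finite(ps_at))
    stop_fluoql(paste0("ChlF_PS is masked at %g nm; ",
                       "try the alternate retrieval band (740/760 nm)"),
                lambda_nm)
  energy_to_photon_flux(ps_at, lambda_nm) *
    f_psii_at(decomp, lambda_nm) *
    conversion_factor_fc(basis, lambda_nm)
}
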