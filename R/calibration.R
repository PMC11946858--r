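#' Raw spectrometer frame
#'
#' Digital numbers recorded with the light source on (`dn_raw`) and off
#' (`dn_dark`) at a given integration time.
#'
#' @param wavelengths numeric grid, nm.
#' @param dn_raw,dn_dark counts per wavelength, non-negative.
#' @param integration_time integration time in ms, > 0.
#' @param channel optional label carried through errors and output.
#' @return A `raw_spectrum` object.
#' @export
raw_spectrum <- function(wavelengths, dn_raw, dn_dark, integration_time,
                         channel = "unknown") {
  wavelengths <- as.numeric(wavelengths)
  stopifnot(length(dn_raw) == length(wavelengths),
            length(dn_dark) == length(wavelengths))
  if (integration_time <= 0)
    stop_fluoql("integration_time must be > 0 ms (got %g)", integration_time)
  if (any(dn_raw < 0) || any(dn_dark < 0))
    stop_fluoql("digital numbers must be non-negative")
  structure(list(wavelengths = wavelengths, dn_raw = as.numeric(dn_raw),
                 dn_dark = as.numeric(dn_dark),
                 integration_time = integration_time, channel = channel),
            class = "raw_spectrum")
}

#' Derive a cross-calibration curve from a reference radiance
#'
#' The calibration factor at each wavelength is
#' `Cal = Rad / (DN_raw - DN_dark)`, with `Rad` the radiance of the common
#' light source measured by a pre-calibrated spectrometer. Because `Cal`
#' scales inversely with integration time on a linear detector, the stored
#' quantity is `cal_norm = Cal * integration_time` (radiance per count per
#' ms), which is invariant across integration times. Wavelengths whose net
#' signal falls below `min_counts` are masked (`NA`) rather than divided.
#'
#' @param reference_radiance a [spectrum_sample()] of the light source
#'   (mW m-2 nm-1 sr-1), interpolated onto the raw grid if within `grid_tol`.
#' @param raw a [raw_spectrum()] from the spectrometer under calibration.
#' @param min_counts masking threshold on `DN_raw - DN_dark` (counts).
#' @param grid_tol maximum extrapolation of the reference grid, nm.
#' @return A `calibration_curve` object with `wavelengths` and `cal_norm`.
#' @export
compute_cal <- function(reference_radiance, raw, min_counts = 50,
                        grid_tol = 0.5) {
  stopifnot(inherits(reference_radiance, "spectrum_sample"),
            inherits(raw, "raw_spectrum"))
  dn_net <- raw$dn_raw - raw$dn_dark
  usable <- is.finite(dn_net) & dn_net >= min_counts
  if (!any(usable))
    stop_fluoql("channel %s: no usable wavelengths (all saturated or dark)",
                raw$channel)
  rad <- interp_to_grid(reference_radiance$wavelengths,
                        reference_radiance$values,
                        raw$wavelengths, tol = grid_tol,
                        what = "reference radiance")
  cal_norm <- rep(NA_real_, length(dn_net))
  cal_norm[usable] <- rad[usable] / dn_net[usable] * raw$integration_time
  structure(list(wavelengths = raw$wavelengths, cal_norm = cal_norm),
            class = "calibration_curve")
}

#' Apply a calibration curve to a raw frame
#'
#' `radiance = (DN_raw - DN_dark) * cal_norm / integration_time`; masked
#' calibration wavelengths propagate as `NA`.
#'
#' @param raw a [raw_spectrum()].
#' @param cal a `calibration_curve` from [compute_cal()].
#' @param grid_tol maximum grid extrapolation, nm.
#' @param channel channel label for the output spectrum.
#' @return A [spectrum_sample()] in mW m-2 nm-1 sr-1.
#' @export
apply_cal <- function(raw, cal, grid_tol = 0.5, channel = "Rad_UP") {
  stopifnot(inherits(raw, "raw_spectrum"), inherits(cal, "calibration_curve"))
  if (length(cal$wavelengths) == length(raw$wavelengths) &&
      all(abs(cal$wavelengths - raw$wavelengths) < 1e-9)) {
    cal_norm <- cal$cal_norm  # identical grids: keep masked wavelengths
  } else {
    ok <- !is.na(cal$cal_norm)
    if (!any(ok)) stop_fluoql("calibration curve is fully masked")
    cal_norm <- interp_to_grid(cal$wavelengths[ok], cal$cal_norm[ok],
                               raw$wavelengths, tol = grid_tol,
                               what = "calibration curve")
    # re-mask target wavelengths whose nearest source point was masked
    nearest <- vapply(raw$wavelengths, function(w)
      which.min(abs(cal$wavelengths - w)), integer(1))
    cal_norm[is.na(cal$cal_norm[nearest])] <- NA_real_
  }
  values <- (raw$dn_raw - raw$dn_dark) * cal_norm / raw$integration_time
  values[values < 0 & !is.na(values)] <- 0
  spectrum_sample(raw$wavelengths, values, channel = channel)
}

#' Check detector linearity across integration times
#'
#' On an ideal linear detector `Cal` is proportional to `1/t_int`. For each
#' wavelength, `Cal` is regressed on `1/t_int` (through the origin) and the
#' coefficient of determination is reported; wavelengths with `r2` below
#' `r2_min` are flagged as a quality-control gate.
#'
#' @param cals list of `list(integration_time = , cal = )` pairs, where `cal`
#'   holds per-wavelength calibration factors (`Cal`, not `cal_norm`) on a
#'   shared grid. At least three integration times are required.
#' @param wavelengths shared wavelength grid, nm.
#' @param r2_min flagging threshold on the per-wavelength fit quality.
#' @param rel_tol flagging threshold on the worst relative deviation of a
#'   measured `Cal` from the linear fit.
#' @return A tibble with `wavelength_nm`, `slope` (radiance per count per
#'   ms-1), `r2`, `max_rel_dev`, `flagged`.
#' @export
check_linearity <- function(cals, wavelengths, r2_min = 0.995,
                            rel_tol = 0.02) {
  if (length(cals) < 3)
    stop_fluoql("linearity check needs >= 3 integration times, got %d",
                length(cals))
  t_inv <- vapply(cals, function(x) 1 / x$integration_time, numeric(1))
  cal_mat <- do.call(rbind, lapply(cals, function(x) as.numeric(x$cal)))
  stopifnot(ncol(cal_mat) == length(wavelengths))
  slope <- colSums(cal_mat * t_inv) / sum(t_inv^2)
  fitted <- outer(t_inv, slope)
  ss_res <- colSums((cal_mat - fitted)^2)
  ss_tot <- colSums(cal_mat^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  max_rel_dev <- apply(abs(cal_mat - fitted) / fitted, 2, max)
  tibble::tibble(wavelength_nm = wavelengths, slope = slope, r2 = r2,
                 max_rel_dev = max_rel_dev,
                 flagged = (!is.na(r2) & r2 < r2_min) |
                   max_rel_dev > rel_tol)
}
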