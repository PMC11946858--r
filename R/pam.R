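#' Lake-model fraction of open PSII reaction centers from PAM variables
#'
#' Under the lake model of fully connected PSII antennae,
#' `qL = (Fm' - Fs) / (Fm' - Fo') * Fo' / Fs`. All arguments are vectorized.
#'
#' @param f_m_prime light-adapted maximal fluorescence.
#' @param f_s steady-state fluorescence, `Fo' <= Fs <= Fm'`.
#' @param f_o_prime light-adapted minimal fluorescence.
#' @param clamp_tol relative tolerance within which small ordering
#'   violations (instrument noise) are clamped with a warning.
#' @param on_violation what to do with records violating the ordering by
#'   more than `clamp_tol`: `"error"` (default, strict validation) or
#'   `"drop"` (return `NA` for those records with a warning, the behavior
#'   used for whole-table processing where isolated saturated-light records
#'   near `Fs = Fm'` can invert under noise).
#' @return qL in \[0, 1\] (`NA` for dropped records).
#' @export
ql_pam <- function(f_m_prime, f_s, f_o_prime, clamp_tol = 0.01,
                   on_violation = c("error", "drop")) {
  on_violation <- match.arg(on_violation)
  if (any(f_m_prime <= 0) || any(f_s <= 0) || any(f_o_prime <= 0))
    stop_fluoql("PAM fluorescence values must be positive")
  if (any(f_m_prime <= f_o_prime))
    stop_fluoql("degenerate PAM record: Fm' <= Fo'")
  lo_bad <- f_s < f_o_prime
  hi_bad <- f_s > f_m_prime
  gross <- (lo_bad & f_s < f_o_prime * (1 - clamp_tol)) |
           (hi_bad & f_s > f_m_prime * (1 + clamp_tol))
  if (any(gross)) {
    if (on_violation == "error")
      stop_fluoql("PAM record violates Fo' <= Fs <= Fm' beyond %.1f%% tolerance",
                  clamp_tol * 100)
    warning(sprintf("dropped %d PAM record(s) violating Fo' <= Fs <= Fm' beyond %.1f%% tolerance",
                    sum(gross), clamp_tol * 100))
  }
  small <- (lo_bad | hi_bad) & !gross
  if (any(small))
    warning(sprintf("clamped %d PAM record(s) with small Fs ordering violations",
                    sum(small)))
  f_s <- pmin(pmax(f_s, f_o_prime), f_m_prime)
  out <- (f_m_prime - f_s) / (f_m_prime - f_o_prime) * f_o_prime / f_s
  out[gross] <- NA_real_
  out
}

#' Invert the lake-model qL expression for Fs
#'
#' Closed-form inverse of [ql_pam()]:
#' `Fs = Fm' * Fo' / (qL * (Fm' - Fo') + Fo')`. Used by the synthetic
#' generator to produce PAM records with a prescribed qL.
#'
#' @param ql target qL in (0, 1].
#' @param f_m_prime,f_o_prime light-adapted maximal/minimal fluorescence,
#'   `Fm' > Fo' > 0`.
#' @return Fs in instrument units.
#' @export
invert_ql_to_fs <- function(ql, f_m_prime, f_o_prime) {
  if (any(ql <= 0) || any(ql > 1))
    stop_fluoql("qL must be in (0, 1] for inversion (Fs -> Fm' as qL -> 0)")
  if (any(f_m_prime <= f_o_prime) || any(f_o_prime <= 0))
    stop_fluoql("require Fm' > Fo' > 0")
  f_m_prime * f_o_prime / (ql * (f_m_prime - f_o_prime) + f_o_prime)
}

#' Non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'`, the Stern-Volmer heat-dissipation proxy.
#'
#' @param f_m dark-adapted maximal fluorescence.
#' @param f_m_prime light-adapted maximal fluorescence, `0 < Fm' <= Fm`.
#' @return NPQ >= 0.
#' @export
npq <- function(f_m, f_m_prime) {
  if (any(f_m_prime <= 0))
    stop_fluoql("Fm' must be positive")
  if (any(f_m < f_m_prime))
    stop_fluoql("Fm < Fm' indicates a measurement problem (NPQ would be negative)")
  (f_m - f_m_prime) / f_m_prime
}

#' Broadband PSII fluorescence from PAM variables
#'
#' A PAM-based reference for broadband PSII fluorescence: the absorbed
#' photon flux routed to PSII times a fluorescence quantum yield proxied by
#' `phi_f_max * Fs / Fm`:
#' `ChlF_PSII_PAM = PAR * absorptance * psii_fraction * phi_f_max * Fs / Fm`.
#' The four scale factors are exposed so the relation can be re-anchored to
#' any absolute calibration of the instrument.
#'
#' @param par incident PAR, umol m-2 s-1.
#' @param f_s steady-state fluorescence.
#' @param f_m dark-adapted maximal fluorescence, > 0.
#' @param absorptance leaf absorptance in (0, 1].
#' @param psii_fraction fraction of absorbed light routed to PSII, (0, 1].
#' @param phi_f_max maximal fluorescence quantum yield, (0, 0.2].
#' @return ChlF_PSII_PAM in umol m-2 s-1.
#' @export
chlf_psii_pam <- function(par, f_s, f_m, absorptance = 0.84,
                          psii_fraction = 0.5, phi_f_max = 0.1) {
  if (any(f_m <= 0)) stop_fluoql("Fm must be positive")
  if (any(par < 0)) stop_fluoql("PAR must be non-negative")
  stopifnot(absorptance > 0, absorptance <= 1,
            psii_fraction > 0, psii_fraction <= 1,
            phi_f_max > 0, phi_f_max <= 0.2)
  par * absorptance * psii_fraction * phi_f_max * f_s / f_m
}

#' Append PAM-derived columns to an observation table
#'
#' Computes `qL_PAM`, `NPQ` and `ChlF_PSII_PAM` row-wise from the PAM
#' columns (`F_o`, `F_m`, `F_s`, `F_o_prime`, `F_m_prime`, `PAR`).
#'
#' @param obs observation tibble (see [read_observation_table()]).
#' @param ... scale factors passed to [chlf_psii_pam()].
#' @return `obs` with the three derived columns appended.
#' @export
derive_pam <- function(obs, ...) {
  need <- c("PAR", "F_m", "F_s", "F_o_prime", "F_m_prime")
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop_fluoql("observation table lacks column(s): %s",
                paste(missing, collapse = ", "))
  obs$qL_PAM <- ql_pam(obs$F_m_prime, obs$F_s, obs$F_o_prime,
                       on_violation = "drop")
  obs$NPQ <- npq(obs$F_m, obs$F_m_prime)
  obs$ChlF_PSII_PAM <- chlf_psii_pam(obs$PAR, obs$F_s, obs$F_m, ...)
  obs
}
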