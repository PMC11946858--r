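#' Measurement protocol for one response curve
#'
#' @param curve_kind `"light"`, `"co2"` or `"temperature"`.
#' @param levels ordered environment levels for the varied driver (PAR in
#'   umol m-2 s-1, CO2 in umol mol-1, or leaf temperature in deg C).
#' @param held named list of the fixed drivers (`PAR`, `CO2`, `T_leaf_C`)
#'   for the other two.
#' @return A `protocol_spec` object.
#' @export
protocol_spec <- function(curve_kind = c("light", "co2", "temperature"),
                          levels, held) {
  curve_kind <- match.arg(curve_kind)
  if (length(levels) == 0) stop_fluoql("protocol levels must be non-empty")
  rng <- switch(curve_kind, light = c(0, 2500), co2 = c(0, 2000),
                temperature = c(5, 50))
  if (any(levels < rng[1]) || any(levels > rng[2]))
    stop_fluoql("%s levels outside the instrument-plausible range [%g, %g]",
                curve_kind, rng[1], rng[2])
  structure(list(curve_kind = curve_kind, levels = as.numeric(levels),
                 held = held),
            class = "protocol_spec")
}

#' Standard response-curve protocols
#'
#' The three stabilized-step protocols used throughout: a light response
#' curve at 25 C and 420 umol mol-1 CO2; a CO2 response curve at saturating
#' light (1500 umol m-2 s-1); and a temperature response curve at 1500
#' umol m-2 s-1 and 420 umol mol-1, stepping 15-45 C (the opening repeat of
#' 25 C re-establishes steady state after the CO2 curve).
#'
#' @return list of three [protocol_spec()] objects named `light`, `co2`,
#'   `temperature`.
#' @export
default_protocols <- function() {
  list(
    light = protocol_spec(
      "light", c(30, 50, 100, 200, 400, 600, 900, 1200, 1500, 1800, 2100),
      held = list(CO2 = 420, T_leaf_C = 25)),
    co2 = protocol_spec(
      "co2", c(420, 30, 50, 100, 200, 300, 400, 600, 900, 1200, 1500),
      held = list(PAR = 1500, T_leaf_C = 25)),
    temperature = protocol_spec(
      "temperature", c(25, 15, 20, 25, 30, 35, 40, 45),
      held = list(PAR = 1500, CO2 = 420)))
}

#' Default elementary emission basis
#'
#' PSII emission as a two-Gaussian mixture with the red peak at 686 nm
#' (sigma 9 nm) and the far-red peak at 740 nm (sigma 28 nm, weights
#' 0.40/0.60); PSI as a single far-red component peaking at 730 nm, built
#' as a two-sided Gaussian with a sharp blue-side falloff (sigma 12 nm,
#' hence negligible emission below 700 nm) and a broad far-red vibrational
#' tail (sigma 45 nm). The broad PSI tail makes the PSII share grow from
#' 760 nm towards its own 740 nm peak, as observed in leaf spectra. Both
#' densities are unit-integral on the grid.
#'
#' @param wavelengths grid, nm (default 640-850 at 0.5 nm).
#' @return An [emission_basis()].
#' @export
default_basis <- function(wavelengths = seq(640, 850, by = 0.5)) {
  gauss <- function(mu, sigma) exp(-(wavelengths - mu)^2 / (2 * sigma^2))
  psi_sigma <- ifelse(wavelengths < 730, 12, 45)
  emission_basis(wavelengths,
                 s_psii = 0.40 * gauss(686, 9) / (9 * sqrt(2 * pi)) +
                          0.60 * gauss(740, 28) / (28 * sqrt(2 * pi)),
                 s_psi = exp(-(wavelengths - 730)^2 / (2 * psi_sigma^2)))
}

#' Default leaf optical properties
#'
#' A logistic red-edge in the escape probability `rho + tau`: strong
#' chlorophyll absorption (escape ~ 0.10) around 680 nm rising to ~ 0.94 in
#' the NIR, split 45/55 between reflectance and transmittance.
#'
#' @param wavelengths grid, nm.
#' @return A [leaf_optics()].
#' @export
default_optics <- function(wavelengths = seq(640, 850, by = 0.5)) {
  absorptance <- 0.06 + 0.88 / (1 + exp((wavelengths - 705) / 8))
  escape <- 1 - absorptance
  leaf_optics(wavelengths, rho = 0.45 * escape, tau = 0.55 * escape)
}

#' Per-PFT mean PSII contribution at 760 nm
#'
#' Typical f_PSII_760 means for the seven plant functional types, used as
#' generator defaults when emulating between-PFT spread.
#'
#' @format named numeric vector.
#' @export
pft_f_psii_defaults <- c(ENF = 0.45, EBF = 0.71, DNF = 0.27, DBF = 0.52,
                         SHR = 0.53, GRA = 0.64, CRO = 0.67)

#' Ground-truth parameter set for the synthetic generator
#'
#' Houses every knob of the forward model: the temperature response of m,
#' the saturating light response of broadband PSII fluorescence, the PSII
#' share of total emission, NPQ kinetics, dark-adapted PAM levels, the
#' up/down split of escaping fluorescence, and noise levels.
#'
#' @param ql_params true temperature-response parameters
#'   ([ql_temp_params()]).
#' @param chlf_saturation list `F_max` (umol m-2 s-1) and `K_F`
#'   (umol m-2 s-1): `ChlF_PSII(PAR) = F_max * PAR / (PAR + K_F)`.
#' @param f_psii_true PSII share of total fluorescence at 760 nm: a scalar
#'   in (0, 1], or a vector named by PFT code to emulate between-PFT spread
#'   (see [pft_f_psii_defaults]).
#' @param npq_max,K_npq NPQ saturation plateau and half-saturation PAR:
#'   `NPQ(PAR) = npq_max * PAR / (PAR + K_npq)`.
#' @param pam_base list `F_o`, `F_m` dark-adapted instrument units,
#'   `F_o < F_m`.
#' @param up_down_split fraction of escaping fluorescence emitted upward.
#' @param noise list `spectral_cv`, `pam_cv`: multiplicative Gaussian
#'   coefficients of variation.
#' @param species_cv log-normal between-species spread applied to `F_max`
#'   and `f_psii_true`.
#' @param seed integer RNG seed; the generator is deterministic given the
#'   full parameter set.
#' @return A `truth_params` object.
#' @export
truth_params <- function(ql_params = ql_temp_params(2.0, 5e4, 2e5, 303.15),
                         chlf_saturation = list(F_max = 40, K_F = 600),
                         f_psii_true = 0.56,
                         npq_max = 3.12, K_npq = 72,
                         pam_base = list(F_o = 500, F_m = 2500),
                         up_down_split = 0.6,
                         noise = list(spectral_cv = 0.02, pam_cv = 0.01),
                         species_cv = 0.1,
                         seed = 1L) {
  stopifnot(inherits(ql_params, "ql_temp_params"))
  if (pam_base$F_o >= pam_base$F_m)
    stop_fluoql("invalid pam_base: F_o must be < F_m")
  if (any(f_psii_true <= 0) || any(f_psii_true > 1))
    stop_fluoql("invalid f_psii_true: must lie in (0, 1]")
  if (up_down_split < 0 || up_down_split > 1)
    stop_fluoql("invalid up_down_split: must lie in [0, 1]")
  for (nm in c("F_max", "K_F")) if (chlf_saturation[[nm]] <= 0)
    stop_fluoql("invalid chlf_saturation$%s: must be > 0", nm)
  if (npq_max < 0 || K_npq <= 0)
    stop_fluoql("invalid NPQ parameters: need npq_max >= 0, K_npq > 0")
  if (noise$spectral_cv < 0 || noise$pam_cv < 0)
    stop_fluoql("invalid noise: CVs must be >= 0")
  structure(list(ql_params = ql_params, chlf_saturation = chlf_saturation,
                 f_psii_true = f_psii_true, npq_max = npq_max,
                 K_npq = K_npq, pam_base = pam_base,
                 up_down_split = up_down_split, noise = noise,
                 species_cv = species_cv, seed = as.integer(seed)),
            class = "truth_params")
}

# value of a basis density at a wavelength (grid usually contains it exactly)
basis_at <- function(basis, component, lambda_nm) {
  approx(basis$wavelengths, basis[[component]], xout = lambda_nm)$y
}

#' Simulate a full multi-species response-curve dataset
#'
#' Runs the forward model in the generative direction for every species and
#' protocol step: the peaked temperature function gives m; the saturating
#' light response gives true broadband PSII fluorescence; the qL model gives
#' true qL; PAM variables are produced by inverting the lake-model
#' expression (with `Fm' = Fm / (1 + NPQ)` and the Oxborough-Baker relation
#' `Fo' = Fo / (Fv/Fm + Fo/Fm')`); the photosystem spectrum is an
#' energy-unit mixture of the PSII and PSI bases whose PSII photon integral
#' equals the true broadband value and whose 760 nm PSII share equals the
#' true f_PSII; bidirectional leaf emission follows by applying the escape
#' probability and the up/down split. Multiplicative Gaussian noise is
#' applied last. Ground truth is retained for recovery tests.
#'
#' @param truth a [truth_params()] object.
#' @param protocols list of [protocol_spec()] (default all three standard
#'   curves).
#' @param n_species number of species, >= 1.
#' @param pft_labels PFT codes recycled across species.
#' @param basis emission basis used to build spectra.
#' @param optics leaf optical properties.
#' @return A `fluoql_dataset`: list with `records` (observation tibble),
#'   `spectra` (wavelength grid + per-channel sample-by-wavelength
#'   matrices), `truth` (input parameters), `truth_steps` (per-sample
#'   ground truth), `optics`, `basis`.
#' @export
simulate_dataset <- function(truth, protocols = default_protocols(),
                             n_species = 1, pft_labels = "DBF",
                             basis = default_basis(),
                             optics = default_optics()) {
  stopifnot(inherits(truth, "truth_params"), n_species >= 1)
  if (!is.null(.GlobalEnv$.Random.seed)) {
    old_seed <- .GlobalEnv$.Random.seed
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(truth$seed)

  wl <- basis$wavelengths
  rho <- interp_to_grid(optics$wavelengths, optics$rho, wl, what = "optics")
  tau <- interp_to_grid(optics$wavelengths, optics$tau, wl, what = "optics")
  escape <- rho + tau
  # photon-weighted PSII basis integral: converts energy coefficient to
  # full-band photon flux
  psii_photon_int <- trapz(wl, energy_to_photon_flux(basis$s_psii, wl))
  s2_760 <- basis_at(basis, "s_psii", 760)
  s1_760 <- basis_at(basis, "s_psi", 760)

  species <- sprintf("sp%02d", seq_len(n_species))
  pft <- rep_len(pft_labels, n_species)
  f_base <- if (length(truth$f_psii_true) > 1) {
    miss <- setdiff(unique(pft), names(truth$f_psii_true))
    if (length(miss))
      stop_fluoql("invalid f_psii_true: no value for PFT(s) %s",
                  paste(miss, collapse = ", "))
    unname(truth$f_psii_true[pft])
  } else rep(truth$f_psii_true, n_species)

  # species-level log-normal jitter on F_max and f_psii (f capped below 1)
  sdlog <- sqrt(log(1 + truth$species_cv^2))
  f_max_sp <- truth$chlf_saturation$F_max *
    exp(rnorm(n_species, -sdlog^2 / 2, sdlog))
  f_psii_sp <- pmin(f_base * exp(rnorm(n_species, -sdlog^2 / 2, sdlog)),
                    0.99)

  f_o <- truth$pam_base$F_o
  f_m <- truth$pam_base$F_m
  fv_fm <- (f_m - f_o) / f_m

  rec_list <- list()
  truth_list <- list()
  spec_rows <- list(ChlF_UP = list(), ChlF_DOWN = list(),
                    Rad_UP = list(), Rad_DOWN = list())
  ids <- character(0)

  for (s in seq_len(n_species)) {
    for (prot in protocols) {
      for (k in seq_along(prot$levels)) {
        env <- prot$held
        env[[switch(prot$curve_kind, light = "PAR", co2 = "CO2",
                    temperature = "T_leaf_C")]] <- prot$levels[k]
        par <- env$PAR; co2 <- env$CO2; t_c <- env$T_leaf_C
        t_k <- celsius_to_kelvin(t_c)

        m_true <- m_of_temperature(truth$ql_params, t_k)
        chlf_true <- f_max_sp[s] * par / (par + truth$chlf_saturation$K_F)
        ql_true <- ql_mod(chlf_true, m_true)
        npq_true <- truth$npq_max * par / (par + truth$K_npq)
        f_m_pr <- f_m / (1 + npq_true)
        f_o_pr <- f_o / (fv_fm + f_o / f_m_pr)
        f_s <- invert_ql_to_fs(ql_true, f_m_pr, f_o_pr)

        # spectral forward model (energy units, hemispheric)
        c_psii <- chlf_true / psii_photon_int
        f_sp <- f_psii_sp[s]
        c_psi <- c_psii * s2_760 * (1 - f_sp) / (f_sp * s1_760)
        chlf_ps <- c_psii * basis$s_psii + c_psi * basis$s_psi
        leaving <- chlf_ps * escape / pi   # total directional radiance
        up <- truth$up_down_split * leaving
        down <- (1 - truth$up_down_split) * leaving
        # incident-light channels (placeholder lamp shape; not used by the
        # retrieval, recorded for completeness)
        e_inc <- par * 3e-3 * wl / 700
        rad_up <- rho * e_inc / pi
        rad_down <- tau * e_inc / pi

        # noise
        pcv <- truth$noise$pam_cv
        scv <- truth$noise$spectral_cv
        if (pcv > 0) {
          jit <- function(x) x * (1 + rnorm(length(x), 0, pcv))
          f_s <- jit(f_s); f_m_pr <- jit(f_m_pr); f_o_pr <- jit(f_o_pr)
        }
        if (scv > 0) {
          sjit <- function(x) pmax(x * (1 + rnorm(length(x), 0, scv)), 0)
          up <- sjit(up); down <- sjit(down)
          rad_up <- sjit(rad_up); rad_down <- sjit(rad_down)
        }

        id <- sprintf("%s_%s_%02d", species[s], prot$curve_kind, k)
        ids <- c(ids, id)
        rec_list[[id]] <- tibble::tibble(
          sample_id = id, species = species[s], pft = pft[s],
          curve_kind = prot$curve_kind, PAR = par, T_leaf_C = t_c,
          CO2 = co2, RH = 50,
          F_o = f_o, F_m = f_m, F_s = f_s,
          F_o_prime = f_o_pr, F_m_prime = f_m_pr,
          A_net = 12 * par / (par + 250) * co2 / (co2 + 300),
          g_sw = 0.11 * par / (par + 200), R_d = 1,
          spectra_ref = id)
        truth_list[[id]] <- tibble::tibble(
          sample_id = id, m_true = m_true, chlf_psii_true = chlf_true,
          ql_true = ql_true, npq_true = npq_true, f_psii_true = f_sp)
        spec_rows$ChlF_UP[[id]] <- up
        spec_rows$ChlF_DOWN[[id]] <- down
        spec_rows$Rad_UP[[id]] <- rad_up
        spec_rows$Rad_DOWN[[id]] <- rad_down
      }
    }
  }

  channels <- lapply(spec_rows, function(rows) {
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    m
  })
  structure(list(
    records = dplyr::bind_rows(rec_list),
    spectra = structure(list(wavelengths = wl, channels = channels),
                        class = "fluoql_spectra"),
    truth = truth,
    truth_steps = dplyr::bind_rows(truth_list),
    optics = optics, basis = basis),
    class = "fluoql_dataset")
}

#' @export
print.fluoql_dataset <- function(x, ...) {
  cat(sprintf(
    "<fluoql_dataset> %d records, %d species, %d PFT(s), %d wavelengths\n",
    nrow(x$records), length(unique(x$records$species)),
    length(unique(x$records$pft)), length(x$spectra$wavelengths)))
  invisible(x)
}

#' Extract one spectrum from a dataset
#'
#' @param spectra the `spectra` element of a `fluoql_dataset`.
#' @param sample_id sample identifier.
#' @param channel spectrum channel name.
#' @return A [spectrum_sample()].
#' @export
get_spectrum <- function(spectra, sample_id, channel) {
  stopifnot(inherits(spectra, "fluoql_spectra"))
  m <- spectra$channels[[channel]]
  if (is.null(m) || !sample_id %in% rownames(m))
    stop_fluoql("no %s spectrum stored for sample %s", channel, sample_id)
  spectrum_sample(spectra$wavelengths, m[sample_id, ], channel = channel)
}
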