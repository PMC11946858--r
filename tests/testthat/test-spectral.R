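wl <- seq(640, 850, by = 0.5)

test_that("reabsorption correction matches direct arithmetic and is linear", {
  n <- length(wl)
  up <- spectrum_sample(wl, rep(1.0, n), channel = "ChlF_UP")
  down <- spectrum_sample(wl, rep(0.5, n), channel = "ChlF_DOWN")
  optics <- leaf_optics(wl, rep(0.05, n), rep(0.05, n))
  ps <- photosystem_fluorescence(up, down, optics)
  expect_equal(ps$values, rep(15 * pi, n))  # (1 + 0.5) / 0.1 * pi
  expect_equal(ps$channel, "ChlF_PS")

  # doubling both inputs doubles the output
  up2 <- spectrum_sample(wl, rep(2.0, n), channel = "ChlF_UP")
  down2 <- spectrum_sample(wl, rep(1.0, n), channel = "ChlF_DOWN")
  expect_equal(photosystem_fluorescence(up2, down2, optics)$values,
               2 * ps$values)

  # zero fluorescence stays zero
  z <- spectrum_sample(wl, rep(0, n), channel = "ChlF_UP")
  z2 <- spectrum_sample(wl, rep(0, n), channel = "ChlF_DOWN")
  expect_true(all(photosystem_fluorescence(z, z2, optics)$values == 0))

  # wavelengths below the escape floor are masked
  rho <- rep(0.05, n); rho[1:5] <- 0.005
  tau <- rep(0.05, n); tau[1:5] <- 0.005
  masked <- photosystem_fluorescence(up, down, leaf_optics(wl, rho, tau))
  expect_true(all(is.na(masked$values[1:5])))
  expect_false(anyNA(masked$values[-(1:5)]))
})

test_that("NNLS decomposition recovers exact mixtures", {
  basis <- default_basis()
  y <- 2 * basis$s_psii + 1 * basis$s_psi
  dec <- decompose_psii_psi(spectrum_sample(wl, y, channel = "ChlF_PS"),
                            basis)
  expect_equal(dec$c_psii, 2, tolerance = 1e-8)
  expect_equal(dec$c_psi, 1, tolerance = 1e-8)
  expect_lt(dec$residual_norm, 1e-10)
  expect_true(all(dec$f_psii_by_lambda >= 0 &
                  dec$f_psii_by_lambda <= 1, na.rm = TRUE))

  # pure PSII input: f_PSII is 1 everywhere and coefficients stay >= 0
  pure <- decompose_psii_psi(
    spectrum_sample(wl, 3 * basis$s_psii, channel = "ChlF_PS"), basis)
  expect_equal(pure$c_psi, 0)
  expect_equal(f_psii_at(pure, 760), 1, tolerance = 1e-8)

  expect_error(decompose_psii_psi(
    spectrum_sample(wl, rep(0, length(wl)), channel = "ChlF_PS"), basis),
    "all-zero")
  collinear <- emission_basis(wl, basis$s_psii, basis$s_psii * 2)
  expect_error(decompose_psii_psi(
    spectrum_sample(wl, y, channel = "ChlF_PS"), collinear),
    "ill-conditioned")
})

test_that("f_PSII interpolation matches the mixture ratio; 740 exceeds 760", {
  basis <- default_basis()
  y <- 2 * basis$s_psii + 1 * basis$s_psi
  dec <- decompose_psii_psi(spectrum_sample(wl, y, channel = "ChlF_PS"),
                            basis)
  s2 <- approx(wl, basis$s_psii, 760)$y
  s1 <- approx(wl, basis$s_psi, 760)$y
  expect_equal(f_psii_at(dec, 760), 2 * s2 / (2 * s2 + s1),
               tolerance = 1e-8)
  # PSII emission peaks near 740, so its share there is larger
  expect_gte(f_psii_at(dec, 740), f_psii_at(dec, 760))
  expect_error(f_psii_at(dec, 900), "outside")
})

test_that("energy-to-photon conversion uses the physical constants", {
  expect_equal(energy_to_photon_flux(1, 760), 6.353104e-3, tolerance = 1e-6)
  expect_equal(energy_to_photon_flux(0, 700), 0)
  expect_equal(energy_to_photon_flux(2, 700),
               2 * energy_to_photon_flux(1, 700))
  expect_error(energy_to_photon_flux(1, -5), "positive")
})

test_that("conversion factor f_C: flat-basis value, scale invariance, fine-grid oracle", {
  # flat emission density: photon-weighted integral over 640-850 nm equals
  # (850^2 - 640^2)/2 / lambda, i.e. exactly 210 nm at the 745 nm midpoint
  flat <- emission_basis(wl, rep(1, length(wl)), rep(1, length(wl)))
  expect_equal(conversion_factor_fc(flat, 745), 210, tolerance = 1e-9)

  basis <- default_basis()
  scaled <- emission_basis(wl, basis$s_psii * 10, basis$s_psi)
  expect_equal(conversion_factor_fc(basis, 760),
               conversion_factor_fc(scaled, 760), tolerance = 1e-12)

  # fine-grid quadrature oracle (0.05 nm) for the default basis at 760 nm
  fine <- default_basis(seq(640, 850, by = 0.05))
  expect_equal(conversion_factor_fc(basis, 760),
               conversion_factor_fc(fine, 760), tolerance = 1e-3)
})

test_that("broadband passive estimate is wavelength-invariant on basis-consistent spectra", {
  basis <- default_basis()
  y <- 5 * basis$s_psii + 2 * basis$s_psi
  ps <- spectrum_sample(wl, y, channel = "ChlF_PS")
  dec <- decompose_psii_psi(ps, basis)
  at <- vapply(c(690, 710, 740, 760, 780), function(l)
    chlf_psii_from_passive(ps, dec, basis, lambda_nm = l), numeric(1))
  expect_equal(max(at) / min(at) - 1, 0, tolerance = 1e-6)
  # and equals the PSII photon integral of the mixture
  oracle <- trapz_oracle(wl, energy_to_photon_flux(5 * basis$s_psii, wl))
  expect_equal(at[4], oracle, tolerance = 1e-6)

  z <- spectrum_sample(wl, rep(0, length(wl)), channel = "ChlF_PS")
  expect_error(decompose_psii_psi(z, basis), "all-zero")
})
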