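test_that("default protocols carry the standard level sequences", {
  p <- default_protocols()
  expect_equal(p$light$levels,
               c(30, 50, 100, 200, 400, 600, 900, 1200, 1500, 1800, 2100))
  expect_equal(p$co2$levels,
               c(420, 30, 50, 100, 200, 300, 400, 600, 900, 1200, 1500))
  expect_equal(p$temperature$levels, c(25, 15, 20, 25, 30, 35, 40, 45))
  expect_equal(p$co2$held$PAR, 1500)
  expect_equal(p$temperature$held$PAR, 1500)
  expect_equal(p$temperature$held$CO2, 420)
  expect_error(protocol_spec("light", c(30, 9999), held = list()),
               "range")
  expect_error(protocol_spec("light", numeric(0), held = list()),
               "non-empty")
})

test_that("default emission basis has the dual-peak structure", {
  b <- default_basis()
  expect_equal(trapz_oracle(b$wavelengths, b$s_psii), 1, tolerance = 1e-4)
  expect_equal(trapz_oracle(b$wavelengths, b$s_psi), 1, tolerance = 1e-4)
  # local maxima of the PSII density near 686 and 740 nm
  d <- diff(b$s_psii)
  peaks <- b$wavelengths[which(d[-1] < 0 & d[-length(d)] > 0) + 1]
  expect_true(any(abs(peaks - 686) <= 3))
  expect_true(any(abs(peaks - 740) <= 5))
  # PSI is a far-red emitter: negligible in the red
  at <- function(lam) approx(b$wavelengths, b$s_psi, lam)$y
  expect_lt(at(660), 0.01 * max(b$s_psi))
  psi_peak <- b$wavelengths[which.max(b$s_psi)]
  expect_lt(abs(psi_peak - 730), 5)
})

test_that("default leaf optics show red absorption and NIR escape", {
  o <- default_optics()
  at <- function(lam, what) approx(o$wavelengths, o[[what]], lam)$y
  esc <- function(lam) at(lam, "rho") + at(lam, "tau")
  expect_lt(esc(680), esc(800))
  expect_true(all(o$rho > 0 & o$tau > 0 & o$rho + o$tau < 1))
  expect_gte(esc(760), 0.4)
  expect_lte(esc(760), 0.95)
})

test_that("generator is deterministic given the seed", {
  tp <- truth_params(seed = 99)
  d1 <- simulate_dataset(tp, n_species = 2, pft_labels = c("GRA", "CRO"))
  d2 <- simulate_dataset(tp, n_species = 2, pft_labels = c("GRA", "CRO"))
  expect_identical(d1$records, d2$records)
  expect_identical(d1$spectra$channels, d2$spectra$channels)
  d3 <- simulate_dataset(truth_params(seed = 100), n_species = 2,
                         pft_labels = c("GRA", "CRO"))
  expect_false(identical(d1$records$F_s, d3$records$F_s))
})

test_that("noise-free generator is self-consistent with the analysis modules", {
  ds <- small_dataset()
  obs <- derive_pam(ds$records)
  obs <- derive_passive(obs, ds$spectra, ds$optics, basis = ds$basis)
  truth <- ds$truth_steps[match(obs$sample_id, ds$truth_steps$sample_id), ]
  # lake-model qL recomputed from generated PAM variables equals truth
  expect_equal(obs$qL_PAM, truth$ql_true, tolerance = 1e-9)
  # passive retrieval recovers broadband PSII fluorescence at every step
  rel <- abs(obs$ChlF_PSII_fPSII - truth$chlf_psii_true) /
    truth$chlf_psii_true
  expect_lt(max(rel), 0.005)
  expect_equal(obs$f_PSII_760, truth$f_psii_true, tolerance = 1e-6)
})

test_that("generated responses are monotone in PAR at fixed temperature", {
  ds <- simulate_dataset(noise_free_truth(),
                         protocols = default_protocols()["light"])
  tr <- ds$truth_steps
  expect_true(all(diff(tr$chlf_psii_true) > 0))
  expect_true(all(diff(tr$ql_true) < 0))
})

test_that("NPQ saturates near its plateau at the top of the light curve", {
  ds <- simulate_dataset(noise_free_truth(),
                         protocols = default_protocols()["light"])
  obs <- derive_pam(ds$records)
  npq_top <- obs$NPQ[obs$PAR == 2100]
  expect_lt(abs(npq_top - 3.12) / 3.12, 0.05)
  # and NPQ rises with light
  expect_true(all(diff(obs$NPQ) > 0))
})

test_that("invalid truth parameters are rejected with the field named", {
  expect_error(truth_params(pam_base = list(F_o = 3000, F_m = 2500)), "F_o")
  expect_error(truth_params(f_psii_true = 1.2), "f_psii_true")
  expect_error(truth_params(up_down_split = -0.1), "up_down_split")
  expect_error(truth_params(chlf_saturation = list(F_max = 0, K_F = 600)),
               "F_max")
})

test_that("per-PFT f_PSII values are honoured by the generator", {
  tp <- noise_free_truth(f_psii_true = pft_f_psii_defaults)
  ds <- simulate_dataset(tp, protocols = default_protocols()["light"],
                         n_species = 2, pft_labels = c("EBF", "DNF"))
  obs <- derive_passive(ds$records, ds$spectra, ds$optics, basis = ds$basis)
  ebf <- obs$f_PSII_760[obs$pft == "EBF"]
  dnf <- obs$f_PSII_760[obs$pft == "DNF"]
  expect_equal(ebf, rep(0.71, length(ebf)), tolerance = 1e-6)
  expect_equal(dnf, rep(0.27, length(dnf)), tolerance = 1e-6)
})
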