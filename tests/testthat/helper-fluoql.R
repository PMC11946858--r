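# Shared fixtures: small, noise-free by default, built in code.

noise_free_truth <- function(seed = 1, ...) {
  truth_params(noise = list(spectral_cv = 0, pam_cv = 0), species_cv = 0,
               seed = seed, ...)
}

# compact dataset: 2 species, light + temperature curves
small_dataset <- function(truth = noise_free_truth(),
                          protocols = default_protocols()[c("light",
                                                            "temperature")],
                          n_species = 2,
                          pft_labels = c("DBF", "ENF")) {
  simulate_dataset(truth, protocols = protocols, n_species = n_species,
                   pft_labels = pft_labels)
}

# independent quadrature oracle: dense midpoint rule on the interpolant
# (different rule and grid from the package's native trapezoid)
trapz_oracle <- function(x, y, n = 2e5) {
  f <- stats::approxfun(x, y)
  edges <- seq(min(x), max(x), length.out = n + 1)
  sum(f((edges[-1] + edges[-(n + 1)]) / 2)) * diff(range(x)) / n
}

# ideal linear-detector raw frame for a given radiance and integration time
ideal_raw <- function(wl, rad, t_int, sensitivity = 400, dark = 1000) {
  raw_spectrum(wl, dn_raw = dark + rad * sensitivity * t_int / 100,
               dn_dark = rep(dark, length(wl)), integration_time = t_int)
}
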