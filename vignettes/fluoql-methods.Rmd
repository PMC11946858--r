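---
title: "Methods: from dual-mode fluorescence to the fraction of open PSII centers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dual-mode fluorescence to the fraction of open PSII centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoql)
```

## The problem

The fraction of open Photosystem II reaction centers, $q_L$, controls how
absorbed light is partitioned into electron transport, heat, and
fluorescence. It can be measured at the leaf with pulse-amplitude-modulated
(PAM) fluorometry, but not remotely. Passively induced chlorophyll
fluorescence (SIF), on the other hand, is retrievable from towers,
aircraft and satellites in narrow bands near 740 and 760 nm. `fluoql`
implements the leaf-level machinery needed to connect the two: derive
broadband PSII fluorescence from passive spectra, relate it to PAM-derived
$q_L$, and fit the temperature-dependent relationship so that $q_L$ can be
predicted from fluorescence alone.

## Active side: lake-model quenching analysis

With dark-adapted minimal/maximal fluorescence $F_o, F_m$ and light-adapted
$F_o', F_s, F_m'$, the lake model (fully connected PSII antennae) gives

$$q_{L,\mathrm{PAM}} = \frac{F_m' - F_s}{F_m' - F_o'}\cdot\frac{F_o'}{F_s},
\qquad \mathrm{NPQ} = \frac{F_m - F_m'}{F_m'}.$$

`ql_pam()` validates the ordering $F_o' \le F_s \le F_m'$; violations
within 1 % (typical instrument noise near saturation, where $F_s \to F_m'$)
are clamped with a warning, larger ones are rejected or — during
whole-table processing — dropped as `NA`. Both behaviors are explicit
(`on_violation`), because silent repair of grossly inconsistent PAM records
hides instrument problems.

A PAM-based broadband reference, `chlf_psii_pam()`, is computed as absorbed
PSII photon flux times a fluorescence-yield proxy,
$\mathrm{PAR}\cdot\alpha\cdot\beta_{PSII}\cdot\phi_{F,max}\cdot F_s/F_m$
(defaults $\alpha = 0.84$, $\beta_{PSII} = 0.5$, $\phi_{F,max} = 0.1$).
This is a deliberately simple, fully parameterized relation: each factor is
exposed so the estimate can be re-anchored to any absolute calibration, and
its role in this package is as a correlated reference series for the
passive estimate, not as an absolute standard.

## Passive side: spectra to broadband PSII fluorescence

Leaf-emitted fluorescence is measured from both sides (`ChlF_UP`,
`ChlF_DOWN`, mW m⁻² nm⁻¹ sr⁻¹). Within-leaf reabsorption — strong around
the 686 nm red peak — is corrected by the escape probability
$\rho(\lambda) + \tau(\lambda)$ (leaf reflectance and transmittance):

$$\mathrm{ChlF}_{PS}(\lambda) =
  \frac{\mathrm{ChlF}_{UP} + \mathrm{ChlF}_{DOWN}}{\rho + \tau}\,\pi .$$

The $\pi$ is the Lambertian radiance-to-hemispheric-flux factor;
thereafter `ChlF_PS` is treated as hemispheric spectral flux
(mW m⁻² nm⁻¹). Wavelengths with $\rho+\tau < 0.02$ (default floor) are
masked rather than amplified.

The photosystem-level spectrum mixes PSII and PSI emission. We partition it
by non-negative least squares against fixed elementary emission shapes
$s_{PSII}, s_{PSI}$ (unit-integral spectral densities):

$$\min_{c \ge 0}\ \lVert \mathrm{ChlF}_{PS} - c_{PSII}\,s_{PSII}
  - c_{PSI}\,s_{PSI} \rVert^2, \qquad
f_{PSII}(\lambda) = \frac{c_{PSII}\,s_{PSII}(\lambda)}
  {c_{PSII}\,s_{PSII}(\lambda) + c_{PSI}\,s_{PSI}(\lambda)}.$$

With two columns the active-set solution is closed-form (`nnls2`), so the
decomposition is exact, deterministic and fast. The broadband PSII photon
flux then follows from a single retrieval band $\lambda$ (760 nm, the O₂-A
band, or 740 nm, the Fraunhofer-line region):

$$\mathrm{ChlF}_{PSII} = \mathrm{photon}\big(\mathrm{ChlF}_{PS}(\lambda)\big)
  \cdot f_{PSII}(\lambda) \cdot f_C(\lambda),$$

where $f_C(\lambda)$ converts the single-band PSII photon flux density to
the full 640–850 nm integral using the PSII emission shape, and
`energy_to_photon_flux()` applies $E = hc/\lambda$ with CODATA constants.
For any spectrum exactly composed from the basis, $f_{PSII}\cdot f_C$
cancels the $\lambda$-dependence, so the estimate is band-invariant — a
property the test suite asserts to $10^{-6}$ relative, and the practical
reason the 740/760 nm choice is immaterial.

## The ChlF$_{PSII}$–$q_L$ model and its fitting

$$q_L = \frac{m}{\mathrm{ChlF}_{PSII}^{1/m} + m},\qquad
m(T) = m_{opt}\,\frac{H_d\,e^{H_a \Delta T}}
  {H_d - H_a\left(1 - e^{H_d \Delta T}\right)},\quad
\Delta T = \frac{T - T_{opt}}{T\,R\,T_{opt}}.$$

The first expression gives $q_L = 1$ in darkness and a monotone decline as
fluorescence rises with light — the observed phenomenology. Its typeset
source is ambiguous, so the algebraic reading is isolated in `ql_mod()`
(one line to change if an alternative convention is required). Because
$\mathrm{ChlF}^{1/m}$ is dimensionful, ChlF$_{PSII}$ must enter in
μmol m⁻² s⁻¹; the fitted $m$ absorbs this unit convention.

The second expression is the standard peaked Arrhenius form: activation
energy $H_a$ (J mol⁻¹) drives the rise below the optimum $T_{opt}$ (K),
deactivation $H_d > H_a$ the fall above it, $R = 8.314$ J mol⁻¹ K⁻¹, and
$m(T_{opt}) = m_{opt}$ exactly.

Fitting is two-stage, mirroring how the data are collected:

1. **Stage 1** (`fit_m`): temperature-curve records are binned by nominal
   leaf temperature (±0.5 °C) and $m$ is estimated per bin by bounded 1-D
   least squares (`stats::optimize` on $[0.01, 10]$, tolerance $10^{-10}$)
   of observed $q_{L,\mathrm{PAM}}$ against modeled $q_L$. A single pair is
   accepted — the 1-D model interpolates it exactly — which matters at
   species level where each nominal temperature holds one stabilized step.
2. **Stage 2** (`fit_temperature_params`): `minpack.lm::nlsLM` fits the
   four parameters to the $(T, \hat m)$ points, weighted by per-bin counts,
   restarted over a fixed deterministic grid of initial values (energies
   $H_a \in \{3,8\}\times10^4$, $H_d \in \{1.5,4\}\times10^5$ J mol⁻¹;
   $m_{opt}$ and $T_{opt}$ anchored on the empirical maximum) under box
   constraints $m_{opt} \in (0, 10]$, $H_a \in [10^4, 3\times10^5]$,
   $H_d \in [5\times10^4, 10^6]$, $T_{opt} \in [278, 323]$ K with
   $H_d > H_a$ enforced. The best converged start by weighted RSS wins.
   There are no random restarts, so the fit is reproducible by
   construction. Identifiability is good: noise-free 7-point curves return
   all four parameters to $< 0.1\,\%$, and with 3 % noise on $m$ the median
   $T_{opt}$ error stays below 1 K (asserted at 2 K over 100 seeded
   replicates).

Observed $q_L = 0$ (a saturated step clamped at $F_s = F_m'$) is accepted
by stage 1: it is legitimate data for the least-squares objective even
though the model approaches zero only asymptotically.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` runs the model in the generative direction over the
standard protocols: light steps 30–2100 μmol m⁻² s⁻¹, CO₂ steps
30–1500 μmol mol⁻¹ at saturating light (1500 μmol m⁻² s⁻¹), temperature
steps 15–45 °C at 1500 μmol m⁻² s⁻¹ and 420 μmol mol⁻¹. For each species
and step it computes $m(T)$, a saturating true broadband PSII fluorescence
$F_{max}\,\mathrm{PAR}/(\mathrm{PAR}+K_F)$, the true $q_L$, PAM variables
by exact inversion of the lake model, and spectra by mixing the emission
bases so that (a) the PSII photon integral equals the true broadband value
and (b) $f_{PSII}$ at 760 nm equals the prescribed truth.

Default parameter choices, made once on physiological grounds:

- $m_{opt} = 2.0$, $H_a = 5\times10^4$, $H_d = 2\times10^5$ J mol⁻¹,
  $T_{opt} = 303.15$ K (30 °C) — mid-range values for a warm-temperate
  flora, well inside the fit bounds.
- $F_{max} = 40$, $K_F = 600$ μmol m⁻² s⁻¹ — broadband PSII fluorescence
  reaching ~31 μmol m⁻² s⁻¹ at the top of the light curve, the right order
  for healthy leaves.
- $\mathrm{NPQ}_{max} = 3.12$, $K_{NPQ} = 72$ μmol m⁻² s⁻¹ — chosen so the
  light curve starts near NPQ ≈ 0.92 at 30 μmol m⁻² s⁻¹ and plateaus near
  3.1 at 2100, the canonical shape of an NPQ light response.
- $f_{PSII,760} = 0.56$ scalar default, or per-PFT means
  (`pft_f_psii_defaults`, 0.27–0.71) to emulate between-type spread.
- $F_o = 500$, $F_m = 2500$ instrument units; $F_o'$ from the
  Oxborough–Baker relation $F_o' = F_o/(F_v/F_m + F_o/F_m')$ — a generator
  convention only; no downstream computation assumes it.
- Noise: multiplicative Gaussian, 2 % per wavelength on spectra, 1 % on
  PAM variables (instrument noise is signal-proportional); species-level
  log-normal jitter (CV 10 %) on $F_{max}$ and $f_{PSII}$.
- Emission bases: PSII as two Gaussians (686 nm, σ = 9 nm; 740 nm,
  σ = 28 nm; weights 0.40/0.60); PSI peaking at 730 nm with a sharp
  blue-side falloff (σ = 12 nm) and a broad far-red vibrational tail
  (σ = 45 nm). The asymmetry is what makes $f_{PSII,740} > f_{PSII,760}$,
  as observed in leaves, while keeping PSI emission negligible below
  700 nm.
- Leaf optics: logistic red edge in $\rho+\tau$ from ~0.10 at 680 nm to
  ~0.94 in the NIR, split 45/55 between reflectance and transmittance.
- Wavelength grid 640–850 nm at 0.5 nm — finer than needed for the
  integrals involved (a 0.05 nm quadrature oracle agrees to <0.1 %),
  configurable.

The generator does **not** emulate: mechanistic gas exchange (A_net and
g_sw are saturating placeholders, never used by the fitted model),
chloroplast-movement effects on reflected radiance, wavelength-dependent
instrument response, stray light or detector nonlinearity, or any
violation of the lake model itself. Passing tests therefore demonstrate
internal consistency and correct inference under the stated forward model
— not that the lake model or the two-basis decomposition is an adequate
description of any particular real leaf.

## Numerical and design choices

- Integrals: trapezoid on the native grid; the fine-grid quadrature in the
  tests is an oracle, not the implementation.
- Grid harmonization: linear interpolation onto the analysis grid,
  tolerance 1 nm (0.5 nm for calibration); beyond that, an error rather
  than silent extrapolation.
- Calibration masking: net signal below 50 counts is masked; masked
  wavelengths propagate as `NA` and are never divided through.
- $R^2$ convention: squared Pearson correlation of the obs–pred scatter by
  default (consistent with reporting slope and intercept alongside);
  `1 - SS_{res}/SS_{tot}` available via `r2 = "ss"`. Sample (n−1) SD in
  the $f_{PSII}$ summaries.
- Ties/degeneracies: all-zero spectra, collinear bases, zero-variance
  observations, sub-minimal point counts and out-of-order PAM records all
  raise specific errors naming the offending quantity.

## Problem sizes

The shipped tests and the acceptance script use 2–21 species (up to 7
functional types × 3 species), the standard 11-step light and 8-step
temperature protocols, a 421-point wavelength grid, and 100-replicate
Monte-Carlo checks for the noisy-recovery properties; a full 21-species
pipeline run takes a few seconds on one core. These sizes give stable
statistics for every asserted property while keeping the suite quick to
run; they are choices of the package, and all of them scale up by
argument.

## Known limitations

- The two-basis decomposition assumes fixed emission shapes; real leaves
  vary in pigment packaging, and PSI contamination of the 686 nm region is
  not separately corrected.
- The PAM-based broadband reference is a parameterized proxy, not an
  absolute standard; its comparison with the passive estimate is
  meaningful up to those scale factors.
- The qL model's $m$ absorbs the ChlF unit convention; parameters fitted
  in other units are not transferable without rescaling.
- Temperature binning assumes the protocol's nominal steps; continuously
  drifting leaf temperature would need a different stage-1 grouping.
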