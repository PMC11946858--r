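# fluoql

Leaf-level tools for estimating the fraction of open Photosystem II
reaction centers (q_L) from simultaneously measured **active** (PAM) and
**passive** (spectrally resolved) chlorophyll fluorescence.

q_L links broadband PSII fluorescence to the actual electron transport rate
from PSII to PSI, and is therefore a key quantity for mechanistic,
fluorescence-based estimation of photosynthesis. PAM fluorometry measures
it directly at the leaf, but only passively induced fluorescence (SIF) can
be observed remotely. `fluoql` implements the full chain that connects the
two:

- **Calibration** — spectrometer digital numbers to radiance via a
  cross-calibration factor `Cal = Rad / (DN_raw − DN_dark)`, stored
  normalized by integration time, with low-signal masking and a detector
  linearity QC check.
- **PAM quenching analysis** — lake-model fraction of open centers
  `q_L = (F_m′ − F_s)/(F_m′ − F_o′) · F_o′/F_s`, non-photochemical
  quenching `NPQ = (F_m − F_m′)/F_m′`, and a PAM-based broadband PSII
  fluorescence reference.
- **Spectral processing** — reabsorption correction of bidirectional leaf
  emission, `ChlF_PS(λ) = (ChlF_UP + ChlF_DOWN)/(ρ + τ) · π`; partition of
  the photosystem-level spectrum into PSII and PSI by non-negative
  least-squares against elementary emission shapes, giving `f_PSII(λ)`;
  and conversion of single-band PSII fluorescence to the broadband photon
  flux `ChlF_PSII = photon(ChlF_PS(λ)) · f_PSII(λ) · f_C(λ)` (retrieval
  band 760 or 740 nm).
- **The ChlF_PSII–q_L model** — `q_L = m / (ChlF_PSII^{1/m} + m)` with the
  shape parameter `m` following a peaked Arrhenius temperature response
  `m(T) = m_opt · H_d · e^{H_a ΔT} / (H_d − H_a(1 − e^{H_d ΔT}))`,
  `ΔT = (T − T_opt)/(T R T_opt)`; fitted in two stages (per-temperature m,
  then the four parameters m_opt, H_a, H_d, T_opt).
- **Evaluation** — R², RMSE, rRMSE, slope and intercept, grouped by plant
  functional type (ENF, EBF, DNF, DBF, SHR, GRA, CRO).
- **Synthetic data** — a generator that runs the whole model in the
  forward direction over the standard light (30–2100 μmol m⁻² s⁻¹), CO₂
  (30–1500 μmol mol⁻¹) and temperature (15–45 °C) response-curve
  protocols, with retained ground truth, so every stage can be validated
  end to end.

## Worked example

```r
library(fluoql)

truth <- truth_params(seed = 42)                      # generator ground truth
ds <- simulate_dataset(truth, n_species = 3,
                       pft_labels = c("DBF", "ENF", "GRA"))
res <- run_pipeline(ds)                               # PAM -> spectra -> fit -> evaluate

res$eval_ql
#> # A tibble: 4 × 7
#>   group    r2   rmse rrmse slope intercept     n
#> 1 DBF   0.984 0.0141  6.83 0.994   0.00531    30
#> 2 ENF   0.979 0.0183  8.27 0.945   0.00770    30
#> 3 GRA   0.980 0.0163  7.22 0.938   0.0162     29
#> 4 all   0.979 0.0163  7.50 0.957   0.00995    89

res$fits[, c("species", "pft", "m_opt", "H_a", "H_d", "T_opt")]
#>   species pft    m_opt      H_a      H_d    T_opt
#> 1    sp01 DBF 1.967521 50770.80 191713.3 302.6338
#> 2    sp02 ENF 1.913816 91214.90 175167.9 302.0010
#> 3    sp03 GRA 2.051132 43766.39 230345.7 303.5621
```

`res$eval_ql` compares the modeled q_L (from passive fluorescence plus the
fitted temperature response) against the PAM-measured q_L: under the
default 1–2 % instrument noise the model explains ~98 % of the q_L
variance with a relative RMSE below 10 %, per functional type and pooled.
`res$fits` shows the recovered temperature-response parameters — close to
the generating truth (m_opt = 2, H_a = 5·10⁴ J mol⁻¹, H_d = 2·10⁵ J mol⁻¹,
T_opt = 303.15 K) but perturbed by noise, as expected from an 8-step
temperature curve. `res$fpsii` summarizes the PSII contribution at 760 nm
per functional type, and `res$eval_chlf` compares the passive broadband
PSII fluorescence against its PAM-based counterpart.

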