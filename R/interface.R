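.obs_required <- c("sample_id", "species", "pft", "PAR", "T_leaf_C",
                   "F_o", "F_m", "F_s", "F_o_prime", "F_m_prime")

.pft_codes <- c("ENF", "EBF", "DNF", "DBF", "SHR", "GRA", "CRO")

# instrument-log header aliases -> canonical schema names
.obs_aliases <- c(
  Tleaf = "T_leaf_C", TleafCnd = "T_leaf_C", Tleaf_C = "T_leaf_C",
  Qin = "PAR", Qamb = "PAR", PARi = "PAR",
  Ca = "CO2", CO2_s = "CO2",
  Fo = "F_o", Fm = "F_m", Fs = "F_s",
  `Fo'` = "F_o_prime", FoPrime = "F_o_prime", Fo_ = "F_o_prime",
  `Fm'` = "F_m_prime", FmPrime = "F_m_prime", Fm_ = "F_m_prime",
  A = "A_net", Anet = "A_net", gsw = "g_sw")

#' Read a stabilized-step observation table
#'
#' Reads the tidy CSV schema written by [write_dataset()] (one row per
#' stabilized response-curve step). Common instrument-log column names
#' (`Tleaf`, `Qin`, `Fo'`, ...) are mapped onto the canonical schema via an
#' alias table. Leaf temperature is stored both in Celsius (`T_leaf_C`) and
#' Kelvin (`T_leaf_K`).
#'
#' @param path CSV file path.
#' @return validated observation tibble.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) stop_fluoql("file not found: %s", path)
  obs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  hit <- names(obs) %in% names(.obs_aliases)
  names(obs)[hit] <- .obs_aliases[names(obs)[hit]]
  missing <- setdiff(.obs_required, names(obs))
  if (length(missing))
    stop_fluoql("observation table %s lacks required column(s): %s",
                path, paste(missing, collapse = ", "))
  if (anyDuplicated(obs$sample_id))
    stop_fluoql("duplicate sample_id values: %s",
                paste(unique(obs$sample_id[duplicated(obs$sample_id)]),
                      collapse = ", "))
  bad_pft <- setdiff(unique(obs$pft), .pft_codes)
  if (length(bad_pft))
    warning(sprintf("unrecognized PFT code(s): %s",
                    paste(bad_pft, collapse = ", ")))
  obs$T_leaf_K <- celsius_to_kelvin(obs$T_leaf_C)
  obs
}

#' Write a dataset to plain-text files
#'
#' Writes `observations.csv` (tidy observation table), `spectra.csv`
#' (long format: sample_id, channel, wavelength_nm, value), `optics.csv`
#' (wavelength_nm, rho, tau) and `truth.json` (generator parameters, for
#' recovery tests) under `dir`.
#'
#' @param dataset a `fluoql_dataset` from [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fluoql_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$records, file.path(dir, "observations.csv"))
  long <- do.call(rbind, lapply(names(dataset$spectra$channels), function(ch) {
    m <- dataset$spectra$channels[[ch]]
    data.frame(sample_id = rep(rownames(m), each = ncol(m)),
               channel = ch,
               wavelength_nm = rep(dataset$spectra$wavelengths, nrow(m)),
               value = as.vector(t(m)))
  }))
  readr::write_csv(long, file.path(dir, "spectra.csv"))
  readr::write_csv(
    data.frame(wavelength_nm = dataset$optics$wavelengths,
               rho = dataset$optics$rho, tau = dataset$optics$tau),
    file.path(dir, "optics.csv"))
  tp <- dataset$truth
  jsonlite::write_json(
    list(ql_params = unclass(tp$ql_params)[c("m_opt", "H_a", "H_d", "T_opt")],
         chlf_saturation = tp$chlf_saturation,
         f_psii_true = as.list(tp$f_psii_true),
         npq_max = tp$npq_max, K_npq = tp$K_npq, pam_base = tp$pam_base,
         up_down_split = tp$up_down_split, noise = tp$noise,
         species_cv = tp$species_cv, seed = tp$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding `observations.csv`, `spectra.csv`,
#'   `optics.csv`.
#' @return list with `records`, `spectra`, `optics` (no ground truth is
#'   reattached), classed `fluoql_dataset`.
#' @export
read_dataset <- function(dir) {
  obs <- read_observation_table(file.path(dir, "observations.csv"))
  long <- readr::read_csv(file.path(dir, "spectra.csv"),
                          show_col_types = FALSE, progress = FALSE)
  wl <- sort(unique(long$wavelength_nm))
  channels <- lapply(split(long, long$channel), function(sub) {
    sub <- sub[order(match(sub$sample_id, obs$sample_id), sub$wavelength_nm), ]
    m <- matrix(sub$value, ncol = length(wl), byrow = TRUE)
    rownames(m) <- unique(sub$sample_id)
    m
  })
  opt <- readr::read_csv(file.path(dir, "optics.csv"),
                         show_col_types = FALSE, progress = FALSE)
  structure(list(
    records = obs,
    spectra = structure(list(wavelengths = wl, channels = channels),
                        class = "fluoql_spectra"),
    optics = leaf_optics(opt$wavelength_nm, opt$rho, opt$tau)),
    class = "fluoql_dataset")
}

#' Append passive-fluorescence columns to an observation table
#'
#' For each record: builds the photosystem-level spectrum from the stored
#' `ChlF_UP`/`ChlF_DOWN` spectra ([photosystem_fluorescence()]),
#' partitions it into PSII/PSI ([decompose_psii_psi()]), and appends
#' `f_PSII_760`, `f_PSII_740`, `decomp_residual` and `ChlF_PSII_fPSII`
#' (at `lambda_nm`).
#'
#' @param obs observation tibble with `spectra_ref` (or `sample_id`) keys.
#' @param spectra `fluoql_spectra` holding the per-sample spectra.
#' @param optics a [leaf_optics()].
#' @param basis an [emission_basis()].
#' @param lambda_nm retrieval wavelength for the broadband estimate.
#' @return `obs` with the passive columns appended.
#' @export
derive_passive <- function(obs, spectra, optics, basis = default_basis(),
                           lambda_nm = 760) {
  key <- if ("spectra_ref" %in% names(obs)) obs$spectra_ref else obs$sample_id
  n <- nrow(obs)
  f760 <- f740 <- chlf <- resid <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    up <- get_spectrum(spectra, key[i], "ChlF_UP")
    down <- get_spectrum(spectra, key[i], "ChlF_DOWN")
    ps <- photosystem_fluorescence(up, down, optics)
    dec <- decompose_psii_psi(ps, basis)
    f760[i] <- f_psii_at(dec, 760)
    f740[i] <- f_psii_at(dec, 740)
    resid[i] <- dec$residual_norm
    chlf[i] <- chlf_psii_from_passive(ps, dec, basis, lambda_nm = lambda_nm)
  }
  obs$f_PSII_760 <- f760
  obs$f_PSII_740 <- f740
  obs$decomp_residual <- resid
  obs$ChlF_PSII_fPSII <- chlf
  obs
}

#' Two-stage fit of the ChlF_PSII-qL model per group
#'
#' Stage 1: temperature-curve records are binned by nominal leaf
#' temperature (0.5 C tolerance) within each group and [fit_m()] estimates
#' m per bin from the `(qL_PAM, ChlF_PSII_fPSII)` pairs. Stage 2:
#' [fit_temperature_params()] fits the peaked temperature function to the
#' `(T, m)` points, weighted by per-bin observation counts.
#'
#' @param obs observation tibble carrying `qL_PAM` and `ChlF_PSII_fPSII`
#'   (run [derive_pam()] and [derive_passive()] first).
#' @param by grouping column: `"species"` (default) or `"pft"`.
#' @param temp_tol nominal-temperature binning tolerance, deg C.
#' @return tibble with one row per group: identifiers, the four fitted
#'   parameters, fit diagnostics, and a `params` list-column of
#'   [ql_temp_params()] objects.
#' @export
fit_ql_temperature <- function(obs, by = "species", temp_tol = 0.5) {
  need <- c("qL_PAM", "ChlF_PSII_fPSII", "curve_kind", "T_leaf_C", by)
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop_fluoql("fit requires column(s): %s", paste(missing, collapse = ", "))
  tc <- obs[obs$curve_kind == "temperature", ]
  if (nrow(tc) == 0)
    stop_fluoql("no temperature-curve records to fit")
  rows <- lapply(split(tc, tc[[by]]), function(sub) {
    bin <- round(sub$T_leaf_C / (2 * temp_tol)) * (2 * temp_tol)
    pts <- lapply(split(sub, bin), function(b) {
      ok <- is.finite(b$qL_PAM) & is.finite(b$ChlF_PSII_fPSII)
      if (!any(ok)) return(NULL)  # bin emptied by dropped PAM records
      fit <- fit_m(b$qL_PAM[ok], b$ChlF_PSII_fPSII[ok])
      data.frame(T_K = celsius_to_kelvin(mean(b$T_leaf_C[ok])),
                 m_hat = fit$m_hat, n_obs = sum(ok))
    })
    pts <- do.call(rbind, pts)
    fit <- fit_temperature_params(pts$T_K, pts$m_hat, weights = pts$n_obs)
    out <- tibble::tibble(
      group = sub[[by]][1],
      pft = if ("pft" %in% names(sub)) sub$pft[1] else NA_character_,
      m_opt = fit$params$m_opt, H_a = fit$params$H_a,
      H_d = fit$params$H_d, T_opt = fit$params$T_opt,
      fit_rmse = fit$rmse, n_points = nrow(pts))
    out$params <- list(fit$params)
    out
  })
  out <- dplyr::bind_rows(rows)
  names(out)[1] <- by
  out
}

#' Predict modeled qL for every record
#'
#' Joins the per-group fitted parameters back onto the observation table
#' and appends `qL_MOD = predict_ql(params, ChlF_PSII_fPSII, T_leaf_K)`.
#'
#' @param obs observation tibble with `ChlF_PSII_fPSII`.
#' @param fits output of [fit_ql_temperature()].
#' @param by grouping column used for the fit.
#' @return `obs` with `qL_MOD` appended.
#' @export
predict_ql_table <- function(obs, fits, by = "species") {
  if (!"T_leaf_K" %in% names(obs))
    obs$T_leaf_K <- celsius_to_kelvin(obs$T_leaf_C)
  idx <- match(obs[[by]], fits[[by]])
  if (anyNA(idx))
    stop_fluoql("no fitted parameters for group(s): %s",
                paste(unique(obs[[by]][is.na(idx)]), collapse = ", "))
  obs$qL_MOD <- vapply(seq_len(nrow(obs)), function(i)
    predict_ql(fits$params[[idx[i]]], obs$ChlF_PSII_fPSII[i],
               obs$T_leaf_K[i]), numeric(1))
  obs
}

#' Run the full analysis chain on a dataset
#'
#' Chains the stages: PAM-derived columns, passive spectral retrieval,
#' two-stage model fitting per group, prediction, and grouped evaluation of
#' modeled against PAM qL and of passive against PAM broadband PSII
#' fluorescence.
#'
#' @param dataset a `fluoql_dataset` (simulated or read from disk).
#' @param lambda_nm retrieval wavelength (740 or 760 nm).
#' @param fit_by grouping for the model fit (`"species"` or `"pft"`).
#' @param basis emission basis (defaults to the dataset's own, else
#'   [default_basis()]).
#' @param ... scale factors forwarded to [derive_pam()].
#' @return list: `records` (table with all derived columns), `fits`,
#'   `eval_ql` (per-PFT + pooled metrics, qL_MOD vs qL_PAM), `eval_chlf`
#'   (ChlF_PSII_fPSII vs ChlF_PSII_PAM), `fpsii` (per-PFT f_PSII_760
#'   summary).
#' @export
run_pipeline <- function(dataset, lambda_nm = 760, fit_by = "species",
                         basis = NULL, ...) {
  stopifnot(inherits(dataset, "fluoql_dataset"))
  if (is.null(basis)) basis <- dataset$basis %||% default_basis()
  obs <- derive_pam(dataset$records, ...)
  obs <- derive_passive(obs, dataset$spectra, dataset$optics,
                        basis = basis, lambda_nm = lambda_nm)
  fits <- fit_ql_temperature(obs, by = fit_by)
  obs <- predict_ql_table(obs, fits, by = fit_by)
  list(records = obs,
       fits = fits,
       eval_ql = evaluate_by_group(obs, "qL_PAM", "qL_MOD"),
       eval_chlf = evaluate_by_group(obs, "ChlF_PSII_PAM", "ChlF_PSII_fPSII"),
       fpsii = summarize_fpsii(obs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
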