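#' Parameter set for the peaked temperature response of m
#'
#' The ChlF_PSII-qL model scales its shape parameter `m` with leaf
#' temperature through a peaked Arrhenius function: an activation-energy
#' rise (`H_a`) below the optimum and a deactivation fall (`H_d`) above it,
#' with maximum `m_opt` at `T_opt`.
#'
#' @param m_opt value of m at the optimal temperature, > 0.
#' @param H_a activation energy, J mol-1, > 0.
#' @param H_d deactivation energy, J mol-1, > `H_a`.
#' @param T_opt optimal leaf temperature, K, in \[273, 330\].
#' @return A `ql_temp_params` object.
#' @export
ql_temp_params <- function(m_opt, H_a, H_d, T_opt) {
  if (!is.finite(m_opt) || m_opt <= 0)
    stop_fluoql("m_opt must be > 0 (got %g)", m_opt)
  if (!is.finite(H_a) || H_a <= 0)
    stop_fluoql("H_a must be > 0 (got %g)", H_a)
  if (!is.finite(H_d) || H_d <= H_a)
    stop_fluoql("H_d must exceed H_a (got H_d = %g, H_a = %g)", H_d, H_a)
  if (T_opt < 273 || T_opt > 330)
    stop_fluoql("T_opt must be in [273, 330] K (got %g)", T_opt)
  structure(list(m_opt = m_opt, H_a = H_a, H_d = H_d, T_opt = T_opt,
                 R = GAS_CONSTANT),
            class = "ql_temp_params")
}

#' @export
print.ql_temp_params <- function(x, ...) {
  cat(sprintf(
    "<ql_temp_params> m_opt = %.4g, H_a = %.4g J/mol, H_d = %.4g J/mol, T_opt = %.2f K (%.2f C)\n",
    x$m_opt, x$H_a, x$H_d, x$T_opt, kelvin_to_celsius(x$T_opt)))
  invisible(x)
}

#' Peaked temperature dependence of the model parameter m
#'
#' `m = m_opt * H_d * exp(H_a * dT) / (H_d - H_a * (1 - exp(H_d * dT)))`
#' with `dT = (T - T_opt) / (T * R * T_opt)`. The function peaks exactly at
#' `T_opt` where `m = m_opt`, and `m < m_opt` elsewhere whenever
#' `H_d > H_a > 0`.
#'
#' @param params a [ql_temp_params()] object.
#' @param t_leaf_k leaf temperature(s) in Kelvin, within (250, 340).
#' @return m, dimensionless.
#' @export
m_of_temperature <- function(params, t_leaf_k) {
  stopifnot(inherits(params, "ql_temp_params"))
  if (any(t_leaf_k <= 250) || any(t_leaf_k >= 340))
    stop_fluoql("leaf temperature %g K outside the supported (250, 340) K range",
                t_leaf_k[t_leaf_k <= 250 | t_leaf_k >= 340][1])
  dt <- (t_leaf_k - params$T_opt) / (t_leaf_k * params$R * params$T_opt)
  params$m_opt * params$H_d * exp(params$H_a * dt) /
    (params$H_d - params$H_a * (1 - exp(params$H_d * dt)))
}

#' Model qL from broadband PSII fluorescence
#'
#' `qL = m / (ChlF_PSII^(1/m) + m)`: unity in darkness (all reaction
#' centers open) and strictly decreasing as PSII fluorescence rises with
#' light. ChlF_PSII enters in umol m-2 s-1; the fitted `m` absorbs this
#' unit convention.
#'
#' @param chlf_psii broadband PSII fluorescence, umol m-2 s-1, >= 0.
#' @param m shape parameter, > 0.
#' @return qL in (0, 1].
#' @export
ql_mod <- function(chlf_psii, m) {
  if (any(m <= 0)) stop_fluoql("m must be > 0")
  if (any(chlf_psii < 0)) stop_fluoql("ChlF_PSII must be >= 0")
  m / (chlf_psii^(1 / m) + m)
}

#' Invert the qL model for ChlF_PSII
#'
#' `ChlF_PSII = (m * (1 - qL) / qL)^m`; exact inverse of [ql_mod()], used
#' by the synthetic generator.
#'
#' @param ql qL in (0, 1].
#' @param m shape parameter, > 0.
#' @return ChlF_PSII in umol m-2 s-1.
#' @export
invert_qlmod_to_chlf <- function(ql, m) {
  if (any(ql <= 0) || any(ql > 1))
    stop_fluoql("qL must be in (0, 1] (ChlF_PSII diverges as qL -> 0)")
  if (any(m <= 0)) stop_fluoql("m must be > 0")
  (m * (1 - ql) / ql)^m
}

#' Fit the shape parameter m from (qL, ChlF_PSII) pairs
#'
#' One-dimensional least squares over a fixed bracket
#' (`stats::optimize`, deterministic): minimizes
#' `sum((qL_obs - ql_mod(ChlF_obs, m))^2)` for `m` in `[m_lo, m_hi]`.
#' A single pair is accepted (the 1-D model interpolates it exactly).
#'
#' @param ql_obs observed qL values in (0, 1].
#' @param chlf_obs observed ChlF_PSII, umol m-2 s-1, >= 0.
#' @param m_lo,m_hi search bracket for m.
#' @return list with `m_hat` and `fit_residual` (RMSE of qL).
#' @export
fit_m <- function(ql_obs, chlf_obs, m_lo = 0.01, m_hi = 10) {
  keep <- is.finite(ql_obs) & is.finite(chlf_obs)
  ql_obs <- ql_obs[keep]; chlf_obs <- chlf_obs[keep]
  if (length(ql_obs) < 1)
    stop_fluoql("fit_m needs at least one finite (qL, ChlF) pair")
  if (all(chlf_obs == 0))
    stop_fluoql("degenerate input: all ChlF_PSII are zero (qL = 1 for any m)")
  if (any(ql_obs < 0) || any(ql_obs > 1))
    stop_fluoql("observed qL outside [0, 1]")
  sse <- function(m) sum((ql_obs - ql_mod(chlf_obs, m))^2)
  opt <- optimize(sse, c(m_lo, m_hi), tol = 1e-10)
  list(m_hat = opt$minimum,
       fit_residual = sqrt(opt$objective / length(ql_obs)))
}

#' Fit the peaked temperature response to per-temperature m estimates
#'
#' Nonlinear least squares of [m_of_temperature()] against `(T, m_hat)`
#' points via `minpack.lm::nlsLM`, restarted over a fixed deterministic
#' grid of initial values; the best converged start satisfying the
#' parameter bounds is returned. Requires at least four points spanning
#' >= 15 K.
#'
#' @param t_leaf_k temperatures, K.
#' @param m_hat fitted m at each temperature, > 0.
#' @param weights optional per-point weights (e.g. observation counts).
#' @param bounds named list overriding the default box constraints
#'   `m_opt` (0, 10], `H_a` \[1e4, 3e5\], `H_d` \[5e4, 1e6\],
#'   `T_opt` \[278, 323\] K.
#' @return list with `params` (a [ql_temp_params()]), `rmse`, `n_converged`
#'   (number of successful starts) and `fitted` values.
#' @export
fit_temperature_params <- function(t_leaf_k, m_hat, weights = NULL,
                                   bounds = list()) {
  keep <- is.finite(t_leaf_k) & is.finite(m_hat) & m_hat > 0
  t_leaf_k <- t_leaf_k[keep]; m_hat <- m_hat[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(t_leaf_k) < 4)
    stop_fluoql("temperature fit needs >= 4 points (got %d)", length(t_leaf_k))
  if (diff(range(t_leaf_k)) < 15)
    stop_fluoql("temperature fit needs >= 15 K span (got %.1f K)",
                diff(range(t_leaf_k)))
  b <- modifyList(list(m_opt = c(1e-3, 10), H_a = c(1e4, 3e5),
                       H_d = c(5e4, 1e6), T_opt = c(278, 323)), bounds)
  lower <- vapply(b, `[`, numeric(1), 1)
  upper <- vapply(b, `[`, numeric(1), 2)
  if (is.null(weights)) weights <- rep(1, length(t_leaf_k))
  dat <- data.frame(T = t_leaf_k, m = m_hat)
  Rgas <- GAS_CONSTANT

  # fixed multi-start grid: anchor m_opt/T_opt on the empirical maximum,
  # sweep activation/deactivation energies over typical magnitudes
  t_peak <- t_leaf_k[which.max(m_hat)]
  starts <- expand.grid(
    m_opt = max(m_hat) * c(1, 1.3),
    H_a = c(3e4, 8e4),
    H_d = c(1.5e5, 4e5),
    T_opt = unique(pmin(pmax(c(t_peak, t_peak + 5), 278), 323)))
  starts <- starts[starts$H_d > starts$H_a, , drop = FALSE]
  starts$m_opt <- pmin(pmax(starts$m_opt, lower[1]), upper[1])

  best <- NULL
  n_converged <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        m ~ m_opt * H_d * exp(H_a * (T - T_opt) / (T * Rgas * T_opt)) /
          (H_d - H_a * (1 - exp(H_d * (T - T_opt) / (T * Rgas * T_opt)))),
        data = dat, weights = weights,
        start = as.list(starts[i, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- coef(fit)
    if (cf[["H_d"]] <= cf[["H_a"]]) next
    n_converged <- n_converged + 1L
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, coef = cf, fit = fit)
  }
  if (is.null(best))
    stop_fluoql(paste0(
      "temperature-response fit failed to converge from any of %d starts ",
      "(T range %.1f-%.1f K, m range %.3g-%.3g)"),
      nrow(starts), min(t_leaf_k), max(t_leaf_k), min(m_hat), max(m_hat))
  params <- ql_temp_params(best$coef[["m_opt"]], best$coef[["H_a"]],
                           best$coef[["H_d"]], best$coef[["T_opt"]])
  fitted_m <- m_of_temperature(params, t_leaf_k)
  list(params = params,
       rmse = sqrt(mean((fitted_m - m_hat)^2)),
       n_converged = n_converged,
       fitted = fitted_m)
}

#' Predict qL from fitted parameters
#'
#' Composition of [m_of_temperature()] and [ql_mod()].
#'
#' @param params a [ql_temp_params()] object.
#' @param chlf_psii broadband PSII fluorescence, umol m-2 s-1.
#' @param t_leaf_k leaf temperature, K.
#' @return modeled qL in (0, 1].
#' @export
predict_ql <- function(params, chlf_psii, t_leaf_k) {
  ql_mod(chlf_psii, m_of_temperature(params, t_leaf_k))
}
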