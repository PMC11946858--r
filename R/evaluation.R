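#' Observed-vs-predicted comparison statistics
#'
#' The standard model-evaluation bundle: RMSE, relative RMSE (percent of
#' the observed mean), R-squared, and the slope/intercept of the ordinary
#' least-squares regression of predictions on observations.
#'
#' @param obs,pred numeric vectors of equal length >= 2.
#' @param r2 R-squared convention: `"pearson"` (squared Pearson
#'   correlation of the scatter, the default) or `"ss"` (coefficient of
#'   determination `1 - SS_res / SS_tot`).
#' @return A one-row tibble: `r2`, `rmse`, `rrmse` (percent), `slope`,
#'   `intercept`, `n`.
#' @export
eval_metrics <- function(obs, pred, r2 = c("pearson", "ss")) {
  r2 <- match.arg(r2)
  if (length(obs) != length(pred))
    stop_fluoql("obs (%d) and pred (%d) differ in length",
                length(obs), length(pred))
  keep <- is.finite(obs) & is.finite(pred)
  obs <- obs[keep]; pred <- pred[keep]
  n <- length(obs)
  if (n < 2) stop_fluoql("need >= 2 finite obs/pred pairs (got %d)", n)
  if (sd(obs) == 0) stop_fluoql("zero-variance observations: R2 undefined")
  if (mean(obs) == 0) stop_fluoql("zero-mean observations: rRMSE undefined")
  rmse <- sqrt(mean((pred - obs)^2))
  fit <- lm(pred ~ obs)
  r2_val <- switch(r2,
                   pearson = stats::cor(obs, pred)^2,
                   ss = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2))
  tibble::tibble(r2 = r2_val, rmse = rmse,
                 rrmse = rmse / mean(obs) * 100,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), n = n)
}

#' Grouped evaluation table
#'
#' One [eval_metrics()] row per group (e.g. plant functional type) plus a
#' pooled `"all"` row, mirroring the usual per-PFT comparison tables.
#' Groups with fewer than two usable rows are excluded with a warning.
#'
#' @param table data frame holding observed and predicted columns.
#' @param obs_col,pred_col column names (strings).
#' @param group_col grouping column name (default `"pft"`).
#' @param ... passed to [eval_metrics()] (e.g. `r2 = "ss"`).
#' @return tibble with a `group` column followed by the metric columns.
#' @export
evaluate_by_group <- function(table, obs_col, pred_col, group_col = "pft",
                              ...) {
  for (cl in c(obs_col, pred_col, group_col))
    if (!cl %in% names(table))
      stop_fluoql("column %s absent from the table", cl)
  groups <- split(table, table[[group_col]])
  rows <- lapply(names(groups), function(g) {
    sub <- groups[[g]]
    ok <- is.finite(sub[[obs_col]]) & is.finite(sub[[pred_col]])
    if (sum(ok) < 2) {
      warning(sprintf("group %s has < 2 usable rows; excluded", g))
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(group = g),
                     eval_metrics(sub[[obs_col]], sub[[pred_col]], ...))
  })
  pooled <- dplyr::bind_cols(
    tibble::tibble(group = "all"),
    eval_metrics(table[[obs_col]], table[[pred_col]], ...))
  dplyr::bind_rows(c(rows, list(pooled)))
}

#' Per-group summary of the PSII contribution at 760 nm
#'
#' Mean and sample standard deviation of `f_PSII_760` per group, formatted
#' `"mean +/- sd"` alongside the numeric columns.
#'
#' @param table data frame with an `f_PSII_760` column.
#' @param group_col grouping column name (default `"pft"`).
#' @return tibble with `group`, `mean`, `sd`, `n`, `formatted`.
#' @export
summarize_fpsii <- function(table, group_col = "pft") {
  if (!"f_PSII_760" %in% names(table))
    stop_fluoql("column f_PSII_760 absent from the table")
  groups <- split(table$f_PSII_760, table[[group_col]])
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]][is.finite(groups[[g]])]
    if (length(v) == 0) return(NULL)
    tibble::tibble(group = g, mean = mean(v),
                   sd = if (length(v) > 1) sd(v) else 0,
                   n = length(v))
  })
  out <- dplyr::bind_rows(rows)
  out$formatted <- sprintf("%.2f ± %.2f", out$mean, out$sd)
  out
}
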