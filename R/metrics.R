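## Metrics module: fit-quality statistics and corrected-AIC model ranking.

#' Average absolute relative deviation, in percent
#'
#' AARD% = (100/n) * sum(|y_calc - y_exp| / y_exp); the field's standard
#' headline statistic for solubility correlations.
#'
#' @param y_exp experimental values, all > 0.
#' @param y_calc model values, same length.
#' @return AARD in percent.
#' @examples
#' aard_percent(c(1e-5, 2e-5), c(1.1e-5, 1.8e-5)) # 10
#' @export
aard_percent <- function(y_exp, y_calc) {
  if (length(y_exp) != length(y_calc) || length(y_exp) < 1) {
    stop_domain("y_exp and y_calc must have equal length >= 1")
  }
  if (any(y_exp <= 0)) stop_domain("all y_exp must be > 0")
  100 * mean(abs(y_calc - y_exp) / y_exp)
}

#' Corrected Akaike information criterion
#'
#' AICc = n ln(sigma^2) + 2Q + 2Q(Q+1)/(n-Q-1) with sigma^2 = SSE/n, the
#' maximum-likelihood error variance. Lower is better; the small-sample
#' term penalizes parameter count Q at small n.
#'
#' @param sse residual sum of squares (> 0).
#' @param n number of observations (> q + 1).
#' @param q number of fitted parameters (>= 1).
#' @return AICc value.
#' @examples
#' aicc(1.34046e-8, 24, 3)
#' @export
aicc <- function(sse, n, q) {
  if (sse <= 0) stop_domain("sse must be > 0")
  if (q < 1) stop_domain("q must be >= 1")
  if (n <= q + 1) stop_domain("need n > q + 1 for the AICc correction term")
  n * log(sse / n) + 2 * q + 2 * q * (q + 1) / (n - q - 1)
}

#' Coefficient of determination
#'
#' R^2 = 1 - SSE/SST with SST taken about the mean of `y_exp`.
#'
#' @inheritParams aard_percent
#' @return R-squared (<= 1; can be negative for fits worse than the mean).
#' @export
r_squared <- function(y_exp, y_calc) {
  if (length(y_exp) != length(y_calc) || length(y_exp) < 2) {
    stop_domain("y_exp and y_calc must have equal length >= 2")
  }
  sst <- sum((y_exp - mean(y_exp))^2)
  if (sst == 0) stop_domain("y_exp has zero variance")
  1 - sum((y_calc - y_exp)^2) / sst
}

#' Adjusted R-squared
#'
#' @param r2 plain R-squared.
#' @param n number of observations.
#' @param q number of fitted parameters.
#' @return Adjusted R-squared.
#' @export
r_squared_adj <- function(r2, n, q) {
  if (n <= q + 1) stop_domain("need n > q + 1")
  1 - (1 - r2) * (n - 1) / (n - q - 1)
}

#' Fit-quality report for one model
#'
#' @inheritParams aard_percent
#' @param model_id model identifier carried into the report.
#' @param q number of fitted parameters.
#' @return A one-row data frame: `model_id`, `aard_percent`, `sse`, `rmse`,
#'   `r2`, `r2_adj`, `aicc`, `n`, `q`.
#' @export
metrics_report <- function(y_exp, y_calc, model_id = NA_character_, q) {
  n <- length(y_exp)
  sse <- sum((y_calc - y_exp)^2)
  data.frame(
    model_id = model_id,
    aard_percent = aard_percent(y_exp, y_calc),
    sse = sse,
    rmse = sqrt(sse / n),
    r2 = r_squared(y_exp, y_calc),
    r2_adj = r_squared_adj(r_squared(y_exp, y_calc), n, q),
    # a numerically perfect fit has sigma^2 = 0; report the -Inf limit
    aicc = if (sse > 0) aicc(sse, n, q) else -Inf,
    n = n,
    q = q,
    stringsAsFactors = FALSE
  )
}

#' Rank model reports by corrected AIC
#'
#' Sorts ascending by `aicc` (best first); ties broken by `aard_percent`,
#' then alphabetically by `model_id`.
#'
#' @param reports a data frame of [metrics_report()] rows.
#' @return The same data frame, reordered.
#' @export
rank_models <- function(reports) {
  if (nrow(reports) < 1) stop_domain("need at least one report")
  reports[order(reports$aicc, reports$aard_percent, reports$model_id), ,
          drop = FALSE]
}

#' Fit and compare all (or selected) models on one dataset
#'
#' Every model is fitted twice: once minimizing AARD (the reported
#' `aard_percent`) and once minimizing squared error in mole-fraction space
#' (the reported `sse`, `rmse`, `r2`, `r2_adj` and the variance-based
#' `aicc`). The returned table is ranked by AICc.
#'
#' @param dataset a `solubility_dataset`.
#' @param models character vector of model ids, or `"all"`.
#' @param config a [fit_config()]; its `objective` field is overridden per
#'   column as described.
#' @param constants a [substance_constants()].
#' @return A ranked data frame (one row per model) with attribute `fits`:
#'   a list with `aard` and `sse_y` fit objects per model.
#' @export
compare_models <- function(dataset, models = "all", config = fit_config(),
                           constants = substance_constants()) {
  if (identical(models, "all")) models <- model_ids()
  fits <- list()
  rows <- lapply(models, function(id) {
    cfg_a <- config; cfg_a$objective <- "aard"
    cfg_s <- config; cfg_s$objective <- "sse_y"
    fa <- fit_model(dataset, id, cfg_a, constants)
    fs <- fit_model(dataset, id, cfg_s, constants)
    fits[[id]] <<- list(aard = fa, sse_y = fs)
    out <- fs$metrics
    out$aard_percent <- fa$metrics$aard_percent
    out
  })
  tab <- rank_models(do.call(rbind, rows))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
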