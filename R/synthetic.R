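## Synthetic module: noisy datasets generated from any registered model,
## for parameter-recovery and estimator-bias studies.

table2_grid <- function() {
  d <- load_dataset("builtin:table2")
  d[, c("temperature_K", "pressure_MPa", "density_kg_m3")]
}

#' Generate a synthetic solubility dataset from a registered model
#'
#' Evaluates the model at each grid point and perturbs it with either
#' multiplicative lognormal noise, y_i = f_i * exp(eps_i) with
#' eps_i ~ N(0, noise_level), or additive Gaussian noise with standard
#' deviation `noise_level * f_i` (redrawn, with a message, if a draw lands
#' at or below zero). Deterministic given `seed`.
#'
#' The default grid is the packaged dataset's 24 (T, P, rho) triples, so
#' synthetic studies share the real experimental design. The default noise
#' level, 2% relative, reflects the < 5% relative standard uncertainty
#' typical of sampling-loop solubility measurements.
#'
#' @param model_id one of [model_ids()].
#' @param true_parameters parameter vector for the generating model.
#' @param grid data frame with `temperature_K`, `pressure_MPa`,
#'   `density_kg_m3`; default the packaged grid.
#' @param noise_model `"multiplicative_lognormal"` or `"additive_gaussian"`.
#' @param noise_level relative noise fraction (>= 0).
#' @param seed RNG seed.
#' @param constants a [substance_constants()].
#' @param label dataset label.
#' @return A `solubility_dataset`.
#' @examples
#' s <- synthetic_dataset("chrastil", c(kappa = 7, E0 = -28, E1 = -7000),
#'                        noise_level = 0, seed = 1)
#' @export
synthetic_dataset <- function(model_id, true_parameters, grid = NULL,
                              noise_model = c("multiplicative_lognormal",
                                              "additive_gaussian"),
                              noise_level = 0.02, seed = 1,
                              constants = substance_constants(),
                              label = NULL) {
  noise_model <- match.arg(noise_model)
  if (noise_level < 0) stop_domain("noise_level must be >= 0")
  if (is.null(grid)) grid <- table2_grid()
  stopifnot(all(c("temperature_K", "pressure_MPa", "density_kg_m3") %in%
                  names(grid)), nrow(grid) > 0)
  mu <- predict_solubility(model_id, grid, true_parameters, constants)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop_domain("model prediction non-positive or non-finite at a grid ",
                "point; choose parameters with positive predictions")
  }
  y <- with_seed(seed, {
    if (noise_model == "multiplicative_lognormal") {
      mu * exp(stats::rnorm(length(mu), 0, noise_level))
    } else {
      out <- mu + stats::rnorm(length(mu), 0, noise_level * mu)
      tries <- 0L
      while (any(out <= 0) && tries < 100L) {
        bad <- out <= 0
        out[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, noise_level * mu[bad])
        tries <- tries + 1L
      }
      if (any(out <= 0)) out[out <= 0] <- mu[out <= 0]
      if (tries > 0L) {
        message("additive noise truncated at zero for some draws (",
                tries, " regeneration pass(es))")
      }
      out
    }
  })
  df <- data.frame(temperature_K = grid$temperature_K,
                   pressure_MPa = grid$pressure_MPa,
                   density_kg_m3 = grid$density_kg_m3,
                   mole_fraction = y)
  if (is.null(label)) {
    label <- sprintf("synthetic:%s(noise=%g,seed=%d)", model_id,
                     noise_level, seed)
  }
  solubility_dataset(df, label = label)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly generates noisy datasets from known parameters, refits the
#' model, and summarizes bias and RMSE per parameter and for the derived
#' quantities that matter downstream (fitted AARD; the 1/T-slope enthalpy
#' for the Bartle and Chrastil-type models).
#'
#' @param model_id one of [model_ids()].
#' @param true_parameters generating parameter vector.
#' @param noise_level relative noise fraction.
#' @param n_replicates number of Monte-Carlo replicates (>= 2).
#' @param seed master seed; replicate r uses `seed + r`.
#' @param config a [fit_config()] for the refits.
#' @param constants a [substance_constants()].
#' @param grid optional grid (default: packaged grid).
#' @return A list of class `recovery_study`: `summary` (data frame with
#'   `quantity`, `truth`, `mean_est`, `bias`, `rmse`), `n_failed`, and the
#'   per-replicate estimates.
#' @export
recovery_study <- function(model_id, true_parameters, noise_level = 0.02,
                           n_replicates = 20, seed = 1,
                           config = fit_config(n_starts = 8),
                           constants = substance_constants(),
                           grid = NULL) {
  if (n_replicates < 2) stop_domain("n_replicates must be >= 2")
  m <- model_info(model_id)
  truth <- as_params(true_parameters, m$parameter_names)
  R <- constants$gas_constant
  derived_truth <- derived_quantities(model_id, truth, R)
  ests <- list(); n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    ds <- synthetic_dataset(model_id, truth, grid = grid,
                            noise_level = noise_level, seed = seed + r,
                            constants = constants)
    f <- tryCatch(fit_model(ds, model_id, config, constants),
                  error = function(e) NULL)
    if (is.null(f)) { n_failed <- n_failed + 1L; next }
    est <- c(f$parameters, aard = f$metrics$aard_percent,
             derived_quantities(model_id, f$parameters, R))
    ests[[length(ests) + 1]] <- est
  }
  if (!length(ests)) stop_domain("all replicate fits failed")
  E <- do.call(rbind, ests)
  truth_all <- c(truth, aard = NA_real_, derived_truth)
  summary <- data.frame(
    quantity = colnames(E),
    truth = as.numeric(truth_all[colnames(E)]),
    mean_est = colMeans(E),
    bias = colMeans(E) - as.numeric(truth_all[colnames(E)]),
    rmse = sqrt(colMeans(sweep(E, 2,
      ifelse(is.na(truth_all[colnames(E)]), colMeans(E),
             truth_all[colnames(E)]))^2)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = summary, n_failed = n_failed, estimates = E),
            class = "recovery_study")
}

derived_quantities <- function(model_id, params, gas_constant) {
  switch(model_id,
    bartle = c(dH_vap_kJ_mol =
                 vaporization_enthalpy(params[["G1"]], gas_constant)),
    chrastil = c(dH_total_kJ_mol =
                   total_enthalpy(params[["E1"]], gas_constant)),
    r_chrastil = c(dH_total_kJ_mol =
                     total_enthalpy(params[["F1"]], gas_constant)),
    setNames(numeric(0), character(0))
  )
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("<recovery_study: %d replicate(s) kept, %d failed>\n",
              nrow(x$estimates), x$n_failed))
  print(x$summary, ...)
  invisible(x)
}
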