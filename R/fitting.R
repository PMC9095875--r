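## Fitting module: deterministic multi-start nonlinear regression of any
## registered model against a solubility dataset, globally or per isotherm.
##
## Optimizer contract: per start, a bounded Levenberg-Marquardt pass on the
## residual vector matching the objective, followed by a Nelder-Mead polish
## of the scalar objective. Starts are the model's analytic (linearized)
## start followed by Latin-hypercube draws inside the bounds, so the first
## start is identical whatever n_starts is.

#' Fitting configuration
#'
#' @param objective `"aard"` (mean absolute relative deviation, the
#'   headline statistic; the default), `"sse_y"` (squared error in
#'   mole-fraction space, used for the variance-based AICc table) or
#'   `"sse_log_y"` (squared error in log space).
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed RNG seed driving the Latin-hypercube draws.
#' @param bounds optional list with named numeric vectors `lower` and
#'   `upper` overriding the model's default box.
#' @param tolerance convergence tolerance on the objective.
#' @param max_iterations iteration cap per optimizer pass.
#' @return A `fit_config` object.
#' @export
fit_config <- function(objective = c("aard", "sse_y", "sse_log_y"),
                       n_starts = 64L, seed = 1L, bounds = NULL,
                       tolerance = 1e-10, max_iterations = 1000L) {
  objective <- match.arg(objective)
  if (n_starts < 1) stop_domain("n_starts must be >= 1")
  if (tolerance <= 0) stop_domain("tolerance must be > 0")
  structure(list(objective = objective, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), bounds = bounds,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "fit_config")
}

scalar_objective <- function(objective, y_exp) {
  switch(objective,
    aard = function(pred) {
      if (any(!is.finite(pred))) return(1e10)
      100 * mean(abs(pred - y_exp) / y_exp)
    },
    sse_y = function(pred) {
      if (any(!is.finite(pred))) return(1e10)
      sum((pred - y_exp)^2)
    },
    sse_log_y = function(pred) {
      if (any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
      sum((log(pred) - log(y_exp))^2)
    }
  )
}

residual_fun <- function(objective, y_exp) {
  switch(objective,
    aard = function(pred) (pred - y_exp) / y_exp,
    sse_y = function(pred) pred - y_exp,
    sse_log_y = function(pred) {
      r <- log(pmax(pred, 1e-300)) - log(y_exp)
      r[!is.finite(r)] <- 1e6
      r
    }
  )
}

#' Fit a solubility model to a dataset
#'
#' Estimates the model's parameters by deterministic multi-start nonlinear
#' regression. Identical `(dataset, model_id, config, constants)` always
#' yield an identical result. The MT model is the exception to the
#' multi-start contract: it is linear in its parameters in the
#' `T ln(y2 P)` space and is fitted there by exact ordinary least squares
#' (the conventional MT treatment); metrics are still computed after
#' inverting to mole-fraction space.
#'
#' @param dataset a `solubility_dataset`.
#' @param model_id one of [model_ids()].
#' @param config a [fit_config()].
#' @param constants a [substance_constants()].
#' @return An object of class `scco2_fit`: fitted `parameters`,
#'   `objective_value`, per-record `predictions`, convergence diagnostics
#'   and a `metrics` row (see [metrics_report()]).
#' @examples
#' d <- load_dataset("builtin:table2")
#' f <- fit_model(d, "chrastil", fit_config(n_starts = 8))
#' f$parameters
#' f$metrics$aard_percent
#' @export
fit_model <- function(dataset, model_id, config = fit_config(),
                      constants = substance_constants()) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (nrow(dataset) == 0) stop_domain("dataset is empty")
  m <- model_info(model_id)
  if (nrow(dataset) < m$parameter_count) {
    stop_domain("dataset has fewer records (", nrow(dataset),
                ") than model parameters (", m$parameter_count, ")")
  }
  if (model_id == "mt") {
    return(fit_mt_ols(dataset, config, constants))
  }
  y_exp <- dataset$mole_fraction
  sobj <- scalar_objective(config$objective, y_exp)
  rfun <- residual_fun(config$objective, y_exp)
  sup <- fit_support(model_id)
  lower <- if (!is.null(config$bounds)) config$bounds$lower else m$lower
  upper <- if (!is.null(config$bounds)) config$bounds$upper else m$upper
  lo_int <- sup$to_internal(lower)
  hi_int <- sup$to_internal(upper)

  predict_at <- function(th_int) {
    th <- sup$from_internal(th_int)
    suppressWarnings(m$predict(dataset, th, constants))
  }
  fn_scalar <- function(th_int) {
    if (any(!is.finite(th_int))) return(1e12)
    over <- sum(pmax(0, lo_int - th_int)) + sum(pmax(0, th_int - hi_int))
    if (over > 0) return(1e10 * (1 + over))
    sobj(predict_at(th_int))
  }
  fn_resid <- function(th_int) {
    if (any(!is.finite(th_int))) return(rep(1e6, length(y_exp)))
    r <- rfun(predict_at(th_int))
    r[!is.finite(r)] <- 1e6
    r
  }

  q <- m$parameter_count
  analytic <- suppressWarnings(
    tryCatch(sup$starts(dataset, constants), error = function(e) list())
  )
  analytic <- lapply(analytic, function(s) pmin(pmax(s, lo_int), hi_int))
  n_lhs <- max(0L, config$n_starts - length(analytic))
  starts <- analytic[seq_len(min(length(analytic), config$n_starts))]
  if (n_lhs > 0) {
    grid <- with_seed(config$seed, lhs::randomLHS(n_lhs, q))
    lhs_starts <- lapply(seq_len(n_lhs), function(i) {
      lo_int + grid[i, ] * (hi_int - lo_int)
    })
    starts <- c(starts, lhs_starts)
  }

  best <- NULL
  n_conv <- 0L
  for (i in seq_along(starts)) {
    th0 <- starts[[i]]
    lm_fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0, lower = lo_int, upper = hi_int, fn = fn_resid,
        control = minpack.lm::nls.lm.control(
          maxiter = min(config$max_iterations, 1024L),
          ftol = config$tolerance, ptol = config$tolerance)),
      error = function(e) NULL)
    th1 <- if (!is.null(lm_fit)) lm_fit$par else th0
    nm <- tryCatch(
      stats::optim(th1, fn_scalar, method = "Nelder-Mead",
                   control = list(maxit = 5L * config$max_iterations,
                                  reltol = config$tolerance)),
      error = function(e) list(par = th1, value = fn_scalar(th1),
                               convergence = 1L))
    ok <- is.finite(nm$value) && nm$value < 1e9 &&
      (nm$convergence == 0 || (!is.null(lm_fit) && lm_fit$info %in% 1:3))
    if (ok) n_conv <- n_conv + 1L
    if (is.null(best) || nm$value < best$value) {
      best <- list(par = nm$par, value = nm$value, index = i, converged = ok)
    }
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e9) {
    stop_domain("all ", length(starts), " starts failed to converge for '",
                model_id, "'")
  }
  ## Iterated polish of the winning start: restart Nelder-Mead until the
  ## objective stops improving, so the reported optimum is tight enough for
  ## the convention-compensation identities to hold numerically.
  for (round in seq_len(6L)) {
    nm2 <- tryCatch(
      stats::optim(best$par, fn_scalar, method = "Nelder-Mead",
                   control = list(maxit = 5L * config$max_iterations,
                                  reltol = config$tolerance)),
      error = function(e) NULL)
    if (is.null(nm2) || !is.finite(nm2$value)) break
    gain <- best$value - nm2$value
    if (nm2$value < best$value) best$par <- nm2$par
    best$value <- min(best$value, nm2$value)
    if (gain <= config$tolerance * max(1, abs(best$value))) break
  }
  params <- sup$from_internal(best$par)
  names(params) <- m$parameter_names
  preds <- suppressWarnings(m$predict(dataset, params, constants))
  new_fit(model_id, params, config, preds, y_exp, best$value,
          n_starts = length(starts), n_conv = n_conv,
          best_index = best$index, converged = best$converged,
          scope = "global",
          isotherm = NA_real_)
}

fit_mt_ols <- function(dataset, config, constants) {
  y <- dataset$mole_fraction
  Pu <- dataset$pressure_MPa * constants$mt_pressure_scale
  z <- dataset$temperature_K * log(y * Pu)
  fit <- stats::lm(z ~ dataset$density_kg_m3 + dataset$temperature_K)
  params <- stats::setNames(stats::coef(fit), c("H0", "H1", "H2"))
  preds <- predict_mt(dataset$temperature_K, dataset$pressure_MPa,
                      dataset$density_kg_m3, params, constants)
  sobj <- scalar_objective(config$objective, y)
  new_fit("mt", params, config, preds, y, sobj(preds),
          n_starts = 1L, n_conv = 1L, best_index = 1L, converged = TRUE,
          scope = "global", isotherm = NA_real_)
}

new_fit <- function(model_id, params, config, preds, y_exp, value,
                    n_starts, n_conv, best_index, converged, scope,
                    isotherm) {
  q <- model_info(model_id)$parameter_count
  metrics <- tryCatch(
    metrics_report(y_exp, preds, model_id = model_id, q = q),
    error = function(e) NULL)
  structure(list(
    model_id = model_id,
    parameters = params,
    scope = scope,
    isotherm_temperature = isotherm,
    objective = config$objective,
    objective_value = value,
    predictions = preds,
    residuals = preds - y_exp,
    converged = converged,
    n_starts = n_starts,
    n_starts_converged = n_conv,
    best_start_index = best_index,
    seed = config$seed,
    metrics = metrics
  ), class = "scco2_fit")
}

#' Fit a model separately to each isotherm
#'
#' @inheritParams fit_model
#' @return A named list of `scco2_fit` objects (class `scco2_fit_list`),
#'   one per temperature, in increasing temperature order.
#' @export
fit_per_isotherm <- function(dataset, model_id, config = fit_config(),
                             constants = substance_constants()) {
  m <- model_info(model_id)
  groups <- split_isotherms(dataset)
  for (nm in names(groups)) {
    if (nrow(groups[[nm]]) < m$parameter_count) {
      stop_domain("isotherm ", nm, " K has ", nrow(groups[[nm]]),
                  " points; model '", model_id, "' needs at least ",
                  m$parameter_count)
    }
  }
  fits <- lapply(names(groups), function(nm) {
    f <- fit_model(groups[[nm]], model_id, config, constants)
    f$scope <- "per_isotherm"
    f$isotherm_temperature <- as.numeric(nm)
    f
  })
  names(fits) <- names(groups)
  structure(fits, class = "scco2_fit_list")
}

#' @export
print.scco2_fit <- function(x, ...) {
  cat(sprintf("<scco2_fit %s (%s, objective %s)>\n", x$model_id, x$scope,
              x$objective))
  cat("  parameters: ",
      paste(sprintf("%s = %.6g", names(x$parameters), x$parameters),
            collapse = ", "), "\n")
  cat(sprintf("  objective_value = %.6g; AARD%% = %.3f; converged = %s (%d/%d starts)\n",
              x$objective_value, x$metrics$aard_percent,
              x$converged, x$n_starts_converged, x$n_starts))
  invisible(x)
}

## ---- analytic starts and internal parameterizations -------------------

## The SLE model is optimized over (dCp, s1 = sqrt(a11), s2 = sqrt(a22)):
## the activity-coefficient exponent is the perfect square (s1 u - s2)^2,
## so the sqrt scale removes the cusp at a11*a22 = 0.
fit_support <- function(model_id) {
  identity_sup <- list(
    to_internal = identity, from_internal = identity,
    starts = function(d, k) list()
  )
  sup <- switch(model_id,
    new_model = list(
      to_internal = function(th) {
        c(th[[1]], sqrt(max(th[[2]], 0)), sqrt(max(th[[3]], 0)))
      },
      from_internal = function(th) c(th[[1]], th[[2]]^2, th[[3]]^2),
      starts = function(d, k) starts_new_model(d, k)
    ),
    alwi_garlapati = list(
      to_internal = identity, from_internal = identity,
      starts = function(d, k) {
        Tr <- d$temperature_K / k$solvent_Tc
        rr <- d$density_kg_m3 / k$solvent_rhoc
        co <- safe_lm(log(d$mole_fraction * rr * Tr), cbind(1, 1 / Tr, rr))
        list(co)
      }
    ),
    sodeifian = list(
      to_internal = identity, from_internal = identity,
      starts = function(d, k) {
        X <- cbind(1, d$pressure_MPa^2 / d$temperature_K,
                   log(d$density_kg_m3 * d$temperature_K),
                   d$density_kg_m3 * log(d$density_kg_m3),
                   d$pressure_MPa * log(d$temperature_K),
                   log(d$density_kg_m3) / d$temperature_K)
        list(safe_lm(log(d$mole_fraction), X))
      }
    ),
    reddy_garlapati = list(
      to_internal = identity, from_internal = identity,
      starts = function(d, k) {
        Tr <- d$temperature_K / k$solvent_Tc
        Pr <- d$pressure_MPa / k$solvent_Pc
        X <- cbind(Tr^2, Pr * Tr^2, Pr^2 * Tr^2, 1, Pr, Pr^2)
        list(safe_lm(d$mole_fraction, X))
      }
    ),
    chrastil = list(
      to_internal = identity, from_internal = identity,
      starts = function(d, k) {
        y <- d$mole_fraction
        co <- safe_lm(log(y / (1 - y)),
                      cbind(1, log(d$density_kg_m3), 1 / d$temperature_K))
        list(c(co[2] + 1, co[1], co[3]))
      }
    ),
    r_chrastil = list(
      to_internal = identity, from_internal = identity,
      starts = function(d, k) {
        base <- rchrastil_base(d$temperature_K, d$density_kg_m3, k)
        co <- safe_lm(log(d$mole_fraction),
                      cbind(1, log(base), 1 / d$temperature_K))
        list(c(co[2] + 1, co[1], co[3]))
      }
    ),
    bartle = list(
      to_internal = identity, from_internal = identity,
      starts = function(d, k) {
        lhs_v <- log(d$mole_fraction * d$pressure_MPa / k$bartle_Pref)
        co <- safe_lm(lhs_v, cbind(1, 1 / d$temperature_K,
                                   d$density_kg_m3 - k$bartle_rhoref))
        list(co)
      }
    ),
    identity_sup
  )
  if (is.null(sup)) identity_sup else sup
}

## Least squares with rank-deficiency tolerance: NA coefficients (collinear
## columns, e.g. 1/T against the intercept on a single isotherm) become 0.
safe_lm <- function(y, X) {
  co <- stats::lm.fit(X, y)$coefficients
  co[is.na(co)] <- 0
  unname(co)
}

## Linearized start for the SLE model: ln y - melt(T) is regressed on
## {g(T), u^2/T, u/T} with u = sqrt(v2 rho); the u^2 and u coefficients
## yield s1 and s2 up to the dropped 1/T consistency condition.
starts_new_model <- function(d, k) {
  R <- k$gas_constant
  Tm <- k$solute_melting_temperature
  Tk <- d$temperature_K
  melt <- if (k$melting_term == "printed") {
    6.54 * (1 - Tk / Tm)
  } else {
    6.54 * (1 - Tm / Tk)
  }
  g <- log(Tk / Tm) - 1 + Tm / Tk
  u <- sqrt(k$solute_molar_volume * d$density_kg_m3)
  co <- safe_lm(log(d$mole_fraction) - melt,
                cbind(g, u^2 / Tk, u / Tk, 1 / Tk))
  dCp <- -R * co[1]
  s1 <- sqrt(max(-R * co[2], 1e-6))
  s2 <- max(R * co[3] / (2 * s1), 0)
  list(c(dCp, s1, s2))
}
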