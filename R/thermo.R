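## Thermo module: enthalpies derived from fitted 1/T slopes, crossover
## pressure detection, and the MT self-consistency transform.

#' Vaporization enthalpy from the Bartle 1/T slope
#'
#' The Bartle model's G1 is a van't Hoff-type slope of ln(y2 P) against
#' 1/T; the vaporization enthalpy is -G1 R.
#'
#' @param G1 fitted Bartle slope, K.
#' @param gas_constant J/(mol K).
#' @return Enthalpy in kJ/mol.
#' @examples
#' vaporization_enthalpy(-9052.4) # 75.26 kJ/mol
#' @export
vaporization_enthalpy <- function(G1, gas_constant = 8.314) {
  -G1 * gas_constant / 1000
}

#' Total heat from a Chrastil-type 1/T slope
#'
#' The E1 (Chrastil) or F1 (reformulated Chrastil) slope times -R is the
#' total heat of the dissolution process (vaporization plus solvation),
#' reported with the positive-magnitude convention.
#'
#' @param slope fitted E1 or F1, K.
#' @param gas_constant J/(mol K).
#' @return Enthalpy in kJ/mol.
#' @export
total_enthalpy <- function(slope, gas_constant = 8.314) {
  -slope * gas_constant / 1000
}

#' Solvation enthalpy as total minus vaporization
#'
#' @param total total heat, kJ/mol.
#' @param vaporization vaporization enthalpy, kJ/mol.
#' @return Solvation enthalpy, kJ/mol (negative = exothermic).
#' @export
solvation_enthalpy <- function(total, vaporization) {
  total - vaporization
}

#' Derived enthalpies from Chrastil-type and Bartle fits
#'
#' Fits the Chrastil, reformulated-Chrastil and Bartle models to the
#' dataset and assembles the enthalpy table: total heat from E1 and F1,
#' vaporization enthalpy from G1, and the two solvation enthalpies as
#' differences.
#'
#' @param dataset a `solubility_dataset`.
#' @param config a [fit_config()].
#' @param constants a [substance_constants()].
#' @return A list of class `enthalpy_report`: `table` (data frame with
#'   total/vaporization/solvation rows and their source pair) and `fits`.
#' @export
enthalpy_report <- function(dataset, config = fit_config(),
                            constants = substance_constants()) {
  f_ch <- fit_model(dataset, "chrastil", config, constants)
  f_rc <- fit_model(dataset, "r_chrastil", config, constants)
  f_ba <- fit_model(dataset, "bartle", config, constants)
  R <- constants$gas_constant
  vap <- vaporization_enthalpy(f_ba$parameters[["G1"]], R)
  tot_ch <- total_enthalpy(f_ch$parameters[["E1"]], R)
  tot_rc <- total_enthalpy(f_rc$parameters[["F1"]], R)
  tab <- data.frame(
    source_pair = c("chrastil/bartle", "r_chrastil/bartle"),
    total_kJ_mol = c(tot_ch, tot_rc),
    vaporization_kJ_mol = c(vap, vap),
    solvation_kJ_mol = c(solvation_enthalpy(tot_ch, vap),
                         solvation_enthalpy(tot_rc, vap)),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 fits = list(chrastil = f_ch, r_chrastil = f_rc,
                             bartle = f_ba)),
            class = "enthalpy_report")
}

#' @export
print.enthalpy_report <- function(x, ...) {
  cat("<enthalpy_report> (kJ/mol)\n")
  print(x$table, ...)
  invisible(x)
}

#' Crossover pressure of solubility isotherms
#'
#' Below the crossover pressure solubility falls with temperature (the
#' density effect dominates); above it, it rises (the sublimation-pressure
#' effect dominates). For every pair of isotherms sharing at least two grid
#' pressures, the difference of the linear interpolants of ln(y2) vs P is
#' scanned for sign changes; each sign change is resolved to a crossing
#' pressure by linear interpolation.
#'
#' @param dataset a `solubility_dataset` with >= 2 isotherms.
#' @return A list of class `crossover_result`: `crossings` (data frame with
#'   `T_low`, `T_high`, `pressure_MPa`, `bracket_lo`, `bracket_hi`),
#'   `estimate` (mean crossing pressure, `NA` if none) and `interval` (the
#'   grid interval bracketing the estimate). No sign flip anywhere yields a
#'   "no crossover" result, not an error.
#' @examples
#' crossover_pressure(load_dataset("builtin:table2"))$estimate
#' @export
crossover_pressure <- function(dataset) {
  groups <- split_isotherms(dataset)
  if (length(groups) < 2) stop_domain("need at least two isotherms")
  temps <- as.numeric(names(groups))
  rows <- list()
  for (i in seq_len(length(temps) - 1)) {
    for (j in seq((i + 1), length(temps))) {
      a <- groups[[i]]; b <- groups[[j]]
      common <- intersect(a$pressure_MPa, b$pressure_MPa)
      if (length(common) < 2) next
      common <- sort(common)
      la <- log(a$mole_fraction[match(common, a$pressure_MPa)])
      lb <- log(b$mole_fraction[match(common, b$pressure_MPa)])
      d <- lb - la
      for (kk in seq_len(length(common) - 1)) {
        if (d[kk] == 0 || d[kk] * d[kk + 1] >= 0) next
        frac <- d[kk] / (d[kk] - d[kk + 1])
        rows[[length(rows) + 1]] <- data.frame(
          T_low = temps[i], T_high = temps[j],
          pressure_MPa = common[kk] + frac * (common[kk + 1] - common[kk]),
          bracket_lo = common[kk], bracket_hi = common[kk + 1])
      }
    }
  }
  if (!length(rows)) {
    return(structure(list(crossings = data.frame(), estimate = NA_real_,
                          interval = c(NA_real_, NA_real_)),
                     class = "crossover_result"))
  }
  crossings <- do.call(rbind, rows)
  est <- mean(crossings$pressure_MPa)
  grid <- sort(unique(dataset$pressure_MPa))
  k <- findInterval(est, grid, all.inside = TRUE)
  structure(list(crossings = crossings, estimate = est,
                 interval = c(grid[k], grid[k + 1])),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  if (!nrow(x$crossings)) {
    cat("<crossover_result: no crossover detected>\n")
  } else {
    cat(sprintf("<crossover_result: %d pairwise crossing(s), mean %.2f MPa in [%g, %g]>\n",
                nrow(x$crossings), x$estimate, x$interval[1], x$interval[2]))
  }
  invisible(x)
}

#' MT self-consistency transform
#'
#' Maps each record to (rho1, T ln(y2 P) - H2 T). With the fitted MT
#' parameters, self-consistent data collapse onto the single line
#' H0 + H1 rho1 irrespective of temperature.
#'
#' @param dataset a `solubility_dataset`.
#' @param H2 the MT temperature coefficient (scalar), or an `scco2_fit`
#'   of the MT model from which H2 is taken.
#' @param constants a [substance_constants()] (pressure-unit convention).
#' @return A data frame with `temperature_K`, `density_kg_m3` and
#'   `transformed` (= T ln(y2 P) - H2 T, pressure in the MT unit).
#' @export
mt_consistency_transform <- function(dataset, H2,
                                     constants = substance_constants()) {
  if (inherits(H2, "scco2_fit")) {
    if (H2$model_id != "mt") stop_domain("fit supplied is not an MT fit")
    H2 <- H2$parameters[["H2"]]
  }
  Pu <- dataset$pressure_MPa * constants$mt_pressure_scale
  data.frame(
    temperature_K = dataset$temperature_K,
    density_kg_m3 = dataset$density_kg_m3,
    transformed = dataset$temperature_K * log(dataset$mole_fraction * Pu) -
      H2 * dataset$temperature_K
  )
}
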