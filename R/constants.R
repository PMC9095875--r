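#' Physical constants of the solute/solvent pair
#'
#' Bundles the physical constants and unit conventions every model boundary
#' needs: solute molar mass, melting temperature and molar volume, CO2 molar
#' mass and critical constants, the gas constant, and the reference
#' quantities used by the Bartle, reformulated-Chrastil and MT conventions.
#'
#' Defaults describe pantoprazole sodium sesquihydrate in CO2:
#' M = 432.44 g/mol, Tm = 412 K, v2 = 2.8202e-4 m^3/mol (group-contribution
#' value, taken as a constant), CO2 M = 44.01 g/mol, Tc = 304.13 K,
#' Pc = 7.377 MPa, rhoc = 467.6 kg/m^3. Fit quality is invariant to the
#' convention constants (they are absorbed exactly by the fitted
#' parameters); they are configurable so that the compensation can be
#' demonstrated.
#'
#' @param solute_molar_mass g/mol.
#' @param solute_melting_temperature K.
#' @param solute_molar_volume m^3/mol.
#' @param solvent_molar_mass g/mol.
#' @param solvent_Tc,solvent_Pc,solvent_rhoc CO2 critical constants
#'   (K, MPa, kg/m^3).
#' @param gas_constant J/(mol K).
#' @param bartle_Pref Bartle reference pressure, MPa.
#' @param bartle_rhoref Bartle reference density, kg/m^3.
#' @param rchrastil_f_std reformulated-Chrastil standard-state fugacity, MPa.
#' @param mt_pressure_scale factor converting MPa to the MT model's internal
#'   pressure unit (default 10, i.e. bar). Absorbed exactly by H2.
#' @param melting_term `"printed"` or `"textual"`; which variant of the
#'   6.54 melting-term substitution the SLE model uses (see
#'   [fugacity_ratio()]).
#' @return An object of class `substance_constants` (a validated list).
#' @examples
#' k <- substance_constants()
#' k$solute_melting_temperature
#' @export
substance_constants <- function(solute_molar_mass = 432.44,
                                solute_melting_temperature = 412,
                                solute_molar_volume = 2.8202e-4,
                                solvent_molar_mass = 44.01,
                                solvent_Tc = 304.13,
                                solvent_Pc = 7.377,
                                solvent_rhoc = 467.6,
                                gas_constant = 8.314,
                                bartle_Pref = 0.1,
                                bartle_rhoref = 700,
                                rchrastil_f_std = 0.1,
                                mt_pressure_scale = 10,
                                melting_term = c("printed", "textual")) {
  melting_term <- match.arg(melting_term)
  k <- list(
    solute_molar_mass = solute_molar_mass,
    solute_melting_temperature = solute_melting_temperature,
    solute_molar_volume = solute_molar_volume,
    solvent_molar_mass = solvent_molar_mass,
    solvent_Tc = solvent_Tc,
    solvent_Pc = solvent_Pc,
    solvent_rhoc = solvent_rhoc,
    gas_constant = gas_constant,
    bartle_Pref = bartle_Pref,
    bartle_rhoref = bartle_rhoref,
    rchrastil_f_std = rchrastil_f_std,
    mt_pressure_scale = mt_pressure_scale,
    melting_term = melting_term
  )
  for (nm in setdiff(names(k), "melting_term")) {
    if (!is.numeric(k[[nm]]) || length(k[[nm]]) != 1 || !is.finite(k[[nm]]) ||
        k[[nm]] <= 0) {
      stop_domain("constant '", nm, "' must be a single positive number")
    }
  }
  structure(k, class = "substance_constants")
}

#' Read substance constants from a YAML config file
#'
#' Any field omitted from the file keeps its [substance_constants()] default.
#'
#' @param path path to a YAML file whose keys match the arguments of
#'   [substance_constants()].
#' @return A `substance_constants` object.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(substance_constants))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop_domain("unknown constants in config: ", paste(extra, collapse = ", "))
  }
  do.call(substance_constants, cfg)
}

#' @export
print.substance_constants <- function(x, ...) {
  cat("<substance_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
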