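## Models module: the eight solubility correlations as pure prediction
## functions y2 = f(T, P, rho1; theta), plus the SLE/regular-solution
## internals (fugacity ratio, infinite-dilution activity coefficient).
##
## Unit conventions, fixed package-wide: T in K, P in MPa, rho1 in kg/m^3,
## y2 dimensionless. Each model converts at its own boundary (reduced
## variables, bar for MT, SI for the reformulated Chrastil base).

#' Solid-to-liquid fugacity ratio of the solute
#'
#' The expanded-liquid treatment needs the ratio f2S/f2L of the pure-solute
#' solid and subcooled-liquid fugacities. With a known melting enthalpy
#' `dHm` the constant-dCp form is used:
#' \deqn{\ln(f_2^S/f_2^L) = \frac{\Delta H_m}{RT}\left(\frac{T}{T_m}-1\right)
#'   - \frac{\Delta C_p}{R}\left[\ln\frac{T}{T_m} - T_m\left(\frac{1}{T_m}
#'   - \frac{1}{T}\right)\right].}
#' When `dHm` is `NULL` (sodium-containing solutes, where group-contribution
#' melting enthalpies are unreliable) the first term is replaced by the
#' empirical constant-6.54 substitution. Two variants of that substitution
#' circulate; both are available:
#' `"printed"` uses 6.54(1 - T/Tm), `"textual"` uses 6.54(1 - Tm/T).
#'
#' At T = Tm every bracketed term vanishes and the ratio is exactly 1.
#'
#' @param temperature system temperature, K.
#' @param melting_temperature solute melting temperature Tm, K.
#' @param dHm melting enthalpy, J/mol, or `NULL` for the 6.54 substitution.
#' @param dCp solid/liquid heat-capacity difference, J/(mol K).
#' @param gas_constant J/(mol K).
#' @param melting_term `"printed"` or `"textual"` (only used when
#'   `dHm` is `NULL`).
#' @return Dimensionless fugacity ratio, > 0.
#' @examples
#' fugacity_ratio(412, 412, dCp = 100)          # exactly 1
#' fugacity_ratio(308, 412, dCp = 0)            # printed variant
#' @export
fugacity_ratio <- function(temperature, melting_temperature, dHm = NULL,
                           dCp = 0, gas_constant = 8.314,
                           melting_term = c("printed", "textual")) {
  melting_term <- match.arg(melting_term)
  check_positive(temperature, "temperature")
  check_positive(melting_temperature, "melting_temperature")
  Tk <- temperature; Tm <- melting_temperature; R <- gas_constant
  melt <- if (is.null(dHm)) {
    if (melting_term == "printed") 6.54 * (1 - Tk / Tm) else 6.54 * (1 - Tm / Tk)
  } else {
    dHm / (R * Tk) * (Tk / Tm - 1)
  }
  cp_term <- dCp / R * (log(Tk / Tm) - Tm * (1 / Tm - 1 / Tk))
  clipped_exp(melt - cp_term)
}

#' Infinite-dilution activity coefficient from regular-solution theory
#'
#' Regular-solution theory with solubility parameters written as
#' delta_i = sqrt(a_ii rho_i) and the solute molar volume eliminating the
#' solute density gives
#' \deqn{\gamma_2^\infty = \exp\left[\frac{a_{22} + a_{11} v_2 \rho_1
#'   - 2\sqrt{a_{11}a_{22}}\,(v_2\rho_1)^{1/2}}{RT}\right],}
#' where a11 and a22 are solvent-solvent and solute-solute interaction
#' potentials (both >= 0).
#'
#' @param temperature K.
#' @param density CO2 density rho1, kg/m^3.
#' @param molar_volume solute molar volume v2, m^3/mol.
#' @param a11,a22 interaction potentials, model units; must be >= 0.
#' @param gas_constant J/(mol K).
#' @return Dimensionless activity coefficient, > 0.
#' @export
gamma_infinity <- function(temperature, density, molar_volume, a11, a22,
                           gas_constant = 8.314) {
  check_positive(temperature, "temperature")
  check_positive(density, "density")
  check_positive(molar_volume, "molar_volume")
  if (any(a11 < 0) || any(a22 < 0)) {
    stop_domain("a11 and a22 must be non-negative (square roots are taken)")
  }
  u2 <- molar_volume * density
  expo <- (a22 + a11 * u2 - 2 * sqrt(a11 * a22) * sqrt(u2)) /
    (gas_constant * temperature)
  clipped_exp(expo)
}

#' SLE / regular-solution solubility model
#'
#' The solubility is the fugacity ratio divided by the infinite-dilution
#' activity coefficient: y2 = (f2S/f2L) / gamma2inf. Three adjustable
#' parameters: `dCp` (J/mol K), `a11`, `a22`.
#'
#' @param temperature K.
#' @param density kg/m^3.
#' @param params named numeric vector `c(dCp=, a11=, a22=)`.
#' @param constants a [substance_constants()] object (supplies Tm, v2, R and
#'   the melting-term variant).
#' @return Predicted mole fraction, > 0.
#' @export
predict_new_model <- function(temperature, density, params,
                              constants = substance_constants()) {
  p <- as_params(params, c("dCp", "a11", "a22"))
  fr <- fugacity_ratio(temperature, constants$solute_melting_temperature,
                       dHm = NULL, dCp = p[["dCp"]],
                       gas_constant = constants$gas_constant,
                       melting_term = constants$melting_term)
  g <- gamma_infinity(temperature, density, constants$solute_molar_volume,
                      p[["a11"]], p[["a22"]],
                      gas_constant = constants$gas_constant)
  fr / g
}

#' Alwi-Garlapati reduced-density model
#'
#' y2 = 1/(rho_r T_r) * exp(A0 + A1/T_r + A2 rho_r), with
#' rho_r = rho1/rhoc and T_r = T/Tc.
#'
#' @inheritParams predict_new_model
#' @param params named vector `c(A0=, A1=, A2=)`.
#' @return Predicted mole fraction, > 0.
#' @export
predict_alwi_garlapati <- function(temperature, density, params,
                                   constants = substance_constants()) {
  p <- as_params(params, c("A0", "A1", "A2"))
  check_positive(constants$solvent_Tc, "solvent_Tc")
  check_positive(constants$solvent_rhoc, "solvent_rhoc")
  Tr <- temperature / constants$solvent_Tc
  rr <- density / constants$solvent_rhoc
  (1 / (rr * Tr)) * clipped_exp(p[["A0"]] + p[["A1"]] / Tr + p[["A2"]] * rr)
}

#' Sodeifian et al. empirical model
#'
#' ln y2 = B0 + B1 P^2/T + B2 ln(rho1 T) + B3 rho1 ln(rho1)
#'       + B4 P ln(T) + B5 ln(rho1)/T, with T in K, P in MPa,
#' rho1 in kg/m^3.
#'
#' @param temperature K.
#' @param pressure MPa.
#' @param density kg/m^3.
#' @param params named vector `c(B0=, ..., B5=)`.
#' @return Predicted mole fraction, > 0.
#' @export
predict_sodeifian <- function(temperature, pressure, density, params) {
  p <- as_params(params, paste0("B", 0:5))
  check_positive(temperature, "temperature")
  check_positive(pressure, "pressure")
  check_positive(density, "density")
  lg <- p[["B0"]] + p[["B1"]] * pressure^2 / temperature +
    p[["B2"]] * log(density * temperature) +
    p[["B3"]] * density * log(density) +
    p[["B4"]] * pressure * log(temperature) +
    p[["B5"]] * log(density) / temperature
  clipped_exp(lg)
}

#' Reddy-Garlapati reduced-variable model
#'
#' y2 = (D0 + D1 Pr + D2 Pr^2) Tr^2 + (D3 + D4 Pr + D5 Pr^2), with
#' Pr = P/Pc and Tr = T/Tc. The raw polynomial value is returned; it can be
#' negative for pathological parameters (clamping is a fitting concern, not
#' a prediction one).
#'
#' @param temperature K.
#' @param pressure MPa.
#' @param params named vector `c(D0=, ..., D5=)`.
#' @param constants supplies Tc and Pc.
#' @return Predicted mole fraction (unclamped).
#' @export
predict_reddy_garlapati <- function(temperature, pressure, params,
                                    constants = substance_constants()) {
  p <- as_params(params, paste0("D", 0:5))
  Tr <- temperature / constants$solvent_Tc
  Pr <- pressure / constants$solvent_Pc
  (p[["D0"]] + p[["D1"]] * Pr + p[["D2"]] * Pr^2) * Tr^2 +
    (p[["D3"]] + p[["D4"]] * Pr + p[["D5"]] * Pr^2)
}

#' Chrastil solvato-complex model
#'
#' With x = rho1^(kappa-1) exp(E0 + E1/T), returns y2 = x/(1+x), the
#' mole-fraction form of the classical association model; kappa is the
#' association number and E1 the 1/T slope carrying the total heat.
#'
#' @param temperature K.
#' @param density kg/m^3.
#' @param params named vector `c(kappa=, E0=, E1=)`.
#' @return Predicted mole fraction in (0, 1).
#' @export
predict_chrastil <- function(temperature, density, params) {
  p <- as_params(params, c("kappa", "E0", "E1"))
  check_positive(density, "density")
  check_positive(temperature, "temperature")
  x <- clipped_exp((p[["kappa"]] - 1) * log(density) +
                     p[["E0"]] + p[["E1"]] / temperature)
  x / (1 + x)
}

#' Reformulated (dimensionally consistent) Chrastil model
#'
#' y2 = (R T rho1 / (M_scf f*))^(kappa'-1) exp(F0 + F1/T). The base is made
#' dimensionless with a consistent SI set: R in J/(mol K), rho1 in kg/m^3,
#' M_scf in kg/mol and the standard-state fugacity f* converted from MPa
#' to Pa.
#'
#' @param temperature K.
#' @param density kg/m^3.
#' @param params named vector `c(kappa_p=, F0=, F1=)`.
#' @param constants supplies M_scf, f* and R.
#' @return Predicted mole fraction, > 0.
#' @export
predict_r_chrastil <- function(temperature, density, params,
                               constants = substance_constants()) {
  p <- as_params(params, c("kappa_p", "F0", "F1"))
  check_positive(constants$rchrastil_f_std, "rchrastil_f_std")
  base <- rchrastil_base(temperature, density, constants)
  clipped_exp((p[["kappa_p"]] - 1) * log(base) +
                p[["F0"]] + p[["F1"]] / temperature)
}

rchrastil_base <- function(temperature, density, constants) {
  constants$gas_constant * temperature * density /
    ((constants$solvent_molar_mass / 1000) * (constants$rchrastil_f_std * 1e6))
}

#' Bartle et al. model
#'
#' ln(y2 P / Pref) = G0 + G1/T + G2 (rho1 - rhoref). G1 is a 1/T slope;
#' -G1 R is the vaporization enthalpy (see [vaporization_enthalpy()]).
#'
#' @param temperature K.
#' @param pressure MPa.
#' @param density kg/m^3.
#' @param params named vector `c(G0=, G1=, G2=)`.
#' @param constants supplies Pref (MPa) and rhoref (kg/m^3).
#' @return Predicted mole fraction, > 0.
#' @export
predict_bartle <- function(temperature, pressure, density, params,
                           constants = substance_constants()) {
  p <- as_params(params, c("G0", "G1", "G2"))
  check_positive(pressure, "pressure")
  (constants$bartle_Pref / pressure) *
    clipped_exp(p[["G0"]] + p[["G1"]] / temperature +
                  p[["G2"]] * (density - constants$bartle_rhoref))
}

#' Mendez-Santiago-Teja (MT) model
#'
#' Inverts T ln(y2 P) - H2 T = H0 + H1 rho1 to
#' y2 = exp((H0 + H1 rho1)/T + H2) / P. Pressure enters in the model's
#' internal unit (bar by default, `constants$mt_pressure_scale` times MPa);
#' the choice is absorbed exactly by H2.
#'
#' @param temperature K.
#' @param pressure MPa.
#' @param density kg/m^3.
#' @param params named vector `c(H0=, H1=, H2=)`.
#' @param constants supplies the pressure unit scale.
#' @return Predicted mole fraction, > 0.
#' @export
predict_mt <- function(temperature, pressure, density, params,
                       constants = substance_constants()) {
  p <- as_params(params, c("H0", "H1", "H2"))
  check_positive(temperature, "temperature")
  check_positive(pressure, "pressure")
  Pu <- pressure * constants$mt_pressure_scale
  clipped_exp((p[["H0"]] + p[["H1"]] * density) / temperature + p[["H2"]]) / Pu
}

## Accept either a named vector (any order) or an unnamed vector in
## registry order.
as_params <- function(params, names_expected) {
  params <- unlist(params, use.names = TRUE)
  if (length(params) != length(names_expected)) {
    stop_domain("expected ", length(names_expected), " parameters (",
                paste(names_expected, collapse = ", "), "), got ",
                length(params))
  }
  if (is.null(names(params)) || all(names(params) == "")) {
    names(params) <- names_expected
  } else if (!setequal(names(params), names_expected)) {
    stop_domain("parameter names must be ",
                paste(names_expected, collapse = ", "))
  }
  params[names_expected]
}

#' The model registry
#'
#' @return Character vector of the eight registered model identifiers.
#' @examples
#' model_ids()
#' @export
model_ids <- function() names(MODEL_REGISTRY)

#' Look up a model definition
#'
#' @param model_id one of [model_ids()].
#' @return A list with elements `model_id`, `label`, `parameter_names`,
#'   `parameter_count`, `requires`, `lower`, `upper` (default fitting box)
#'   and `predict(dataset, theta, constants)`.
#' @export
model_info <- function(model_id) {
  if (!model_id %in% names(MODEL_REGISTRY)) {
    stop_domain("unknown model '", model_id, "'; see model_ids()")
  }
  MODEL_REGISTRY[[model_id]]
}

#' Predict solubility for a dataset with a registered model
#'
#' @param model_id one of [model_ids()].
#' @param dataset a `solubility_dataset` (or data frame with the dataset
#'   columns).
#' @param params parameter vector in the model's order (see
#'   [model_info()]`$parameter_names`).
#' @param constants a [substance_constants()] object.
#' @return Numeric vector of predicted mole fractions, one per record.
#' @export
predict_solubility <- function(model_id, dataset, params,
                               constants = substance_constants()) {
  m <- model_info(model_id)
  m$predict(dataset, params, constants)
}

## Default boxes are generous physical ranges (documented in the vignette);
## they bracket both the published constants' magnitudes and the optima
## observed on drug/ScCO2 datasets of this kind.
MODEL_REGISTRY <- list(
  new_model = list(
    model_id = "new_model",
    label = "SLE / regular-solution model",
    parameter_names = c("dCp", "a11", "a22"),
    parameter_count = 3L,
    requires = c("T", "rho1", "constants"),
    lower = c(dCp = -1e5, a11 = 0, a22 = 0),
    upper = c(dCp = 1e5, a11 = 1e7, a22 = 1e6),
    predict = function(d, th, k) {
      predict_new_model(d$temperature_K, d$density_kg_m3, th, k)
    }
  ),
  alwi_garlapati = list(
    model_id = "alwi_garlapati",
    label = "Alwi-Garlapati model",
    parameter_names = c("A0", "A1", "A2"),
    parameter_count = 3L,
    requires = c("T", "rho1", "constants"),
    lower = c(A0 = -100, A1 = -100, A2 = 0),
    upper = c(A0 = 100, A1 = 0, A2 = 30),
    predict = function(d, th, k) {
      predict_alwi_garlapati(d$temperature_K, d$density_kg_m3, th, k)
    }
  ),
  sodeifian = list(
    model_id = "sodeifian",
    label = "Sodeifian et al. model",
    parameter_names = paste0("B", 0:5),
    parameter_count = 6L,
    requires = c("T", "P", "rho1"),
    lower = c(B0 = -50, B1 = -1, B2 = -20, B3 = -0.1, B4 = -1, B5 = -5e4),
    upper = c(B0 = 50, B1 = 1, B2 = 20, B3 = 0.1, B4 = 1, B5 = 5e4),
    predict = function(d, th, k) {
      predict_sodeifian(d$temperature_K, d$pressure_MPa, d$density_kg_m3, th)
    }
  ),
  reddy_garlapati = list(
    model_id = "reddy_garlapati",
    label = "Reddy-Garlapati model",
    parameter_names = paste0("D", 0:5),
    parameter_count = 6L,
    requires = c("T", "P", "constants"),
    lower = setNames(rep(-0.01, 6), paste0("D", 0:5)),
    upper = setNames(rep(0.01, 6), paste0("D", 0:5)),
    predict = function(d, th, k) {
      predict_reddy_garlapati(d$temperature_K, d$pressure_MPa, th, k)
    }
  ),
  chrastil = list(
    model_id = "chrastil",
    label = "Chrastil model",
    parameter_names = c("kappa", "E0", "E1"),
    parameter_count = 3L,
    requires = c("T", "rho1"),
    lower = c(kappa = 1, E0 = -100, E1 = -2e4),
    upper = c(kappa = 20, E0 = 50, E1 = 0),
    predict = function(d, th, k) {
      predict_chrastil(d$temperature_K, d$density_kg_m3, th)
    }
  ),
  r_chrastil = list(
    model_id = "r_chrastil",
    label = "Reformulated Chrastil model",
    parameter_names = c("kappa_p", "F0", "F1"),
    parameter_count = 3L,
    requires = c("T", "rho1", "constants"),
    lower = c(kappa_p = 1, F0 = -150, F1 = -2e4),
    upper = c(kappa_p = 20, F0 = 50, F1 = 0),
    predict = function(d, th, k) {
      predict_r_chrastil(d$temperature_K, d$density_kg_m3, th, k)
    }
  ),
  bartle = list(
    model_id = "bartle",
    label = "Bartle et al. model",
    parameter_names = c("G0", "G1", "G2"),
    parameter_count = 3L,
    requires = c("T", "P", "rho1", "constants"),
    lower = c(G0 = -50, G1 = -3e4, G2 = 0),
    upper = c(G0 = 100, G1 = 0, G2 = 0.1),
    predict = function(d, th, k) {
      predict_bartle(d$temperature_K, d$pressure_MPa, d$density_kg_m3, th, k)
    }
  ),
  mt = list(
    model_id = "mt",
    label = "Mendez-Santiago-Teja model",
    parameter_names = c("H0", "H1", "H2"),
    parameter_count = 3L,
    requires = c("T", "P", "rho1", "constants"),
    lower = c(H0 = -5e4, H1 = 0, H2 = 0),
    upper = c(H0 = 0, H1 = 50, H2 = 100),
    predict = function(d, th, k) {
      predict_mt(d$temperature_K, d$pressure_MPa, d$density_kg_m3, th, k)
    }
  )
)
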