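## Dataset module: the packaged 24-point fixture, CSV I/O, validation, and
## the sampling-loop solubility arithmetic.

DATASET_COLUMNS <- c("temperature_K", "pressure_MPa", "density_kg_m3",
                     "mole_fraction", "solubility_g_L", "std_dev",
                     "expanded_U")

#' Load an isothermal solubility dataset
#'
#' Reads a CSV of (T, P, rho, y2) solubility records, validates it and sorts
#' by (temperature, pressure). `"builtin:table2"` loads the packaged
#' pantoprazole sodium sesquihydrate dataset: 24 records on a 4 x 6 grid
#' (308, 318, 328, 338 K by 12-27 MPa) with CO2 densities and mole fractions
#' exactly as published.
#'
#' Required columns: `temperature_K`, `pressure_MPa`, `density_kg_m3`,
#' `mole_fraction`. Optional: `solubility_g_L`, `std_dev`, `expanded_U`
#' (carried as data; never used in fitting).
#'
#' @param path a CSV file path, or `"builtin:table2"`.
#' @param label dataset label; defaults to the file name.
#' @return A `solubility_dataset`: a validated data frame sorted by
#'   (temperature, pressure) with a `label` attribute.
#' @examples
#' d <- load_dataset("builtin:table2")
#' nrow(d)           # 24
#' range(d$mole_fraction)
#' @export
load_dataset <- function(path, label = NULL) {
  if (identical(path, "builtin:table2")) {
    path <- system.file("extdata", "pantoprazole_scco2_table2.csv",
                        package = "scco2sol", mustWork = TRUE)
    if (is.null(label)) label <- "table2"
  }
  if (!file.exists(path)) stop_domain("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(label)) label <- basename(path)
  solubility_dataset(df, label = label)
}

#' Construct and validate a solubility dataset
#'
#' @param df a data frame with the columns documented in [load_dataset()].
#' @param label character label.
#' @return A `solubility_dataset`.
#' @export
solubility_dataset <- function(df, label = "dataset") {
  required <- DATASET_COLUMNS[1:4]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_domain("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (opt in DATASET_COLUMNS[5:7]) if (!opt %in% names(df)) df[[opt]] <- NA_real_
  df <- df[DATASET_COLUMNS]
  for (col in DATASET_COLUMNS) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad)) {
        stop_domain("non-numeric value in column '", col, "', row ", bad[1])
      }
      df[[col]] <- vn
    }
  }
  check_rows <- function(cond, msg) {
    bad <- which(!is.na(cond) & !cond)
    if (length(bad)) stop_domain("row ", bad[1], ": ", msg)
  }
  check_rows(df$temperature_K > 0, "temperature must be > 0")
  check_rows(df$pressure_MPa > 0, "pressure must be > 0")
  check_rows(df$density_kg_m3 > 0, "density must be > 0")
  check_rows(df$mole_fraction > 0 & df$mole_fraction < 1,
             "mole_fraction must lie strictly in (0, 1)")
  check_rows(is.na(df$solubility_g_L) | df$solubility_g_L > 0,
             "solubility_g_L must be > 0 when present")
  if (anyNA(df$mole_fraction)) {
    stop_domain("row ", which(is.na(df$mole_fraction))[1],
                ": mole_fraction is missing")
  }
  df <- df[order(df$temperature_K, df$pressure_MPa), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label,
            class = c("solubility_dataset", "data.frame"))
}

#' Write a solubility dataset to CSV
#'
#' Numbers are written with full double precision so that
#' `load_dataset(write_dataset(d, f))` reproduces `d` bit-for-bit.
#'
#' @param dataset a `solubility_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  out <- as.data.frame(dataset)
  for (col in names(out)) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = NA)
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into isotherms
#'
#' @param dataset a `solubility_dataset`.
#' @return A named list of `solubility_dataset` objects, one per distinct
#'   temperature, names formatted as the temperature in K.
#' @export
split_isotherms <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  temps <- sort(unique(dataset$temperature_K))
  out <- lapply(temps, function(tt) {
    solubility_dataset(as.data.frame(dataset[dataset$temperature_K == tt, ]),
                       label = paste0(attr(dataset, "label"), "@", tt, "K"))
  })
  names(out) <- format(temps, trim = TRUE)
  out
}

#' Equilibrium mole fraction from sampling-loop quantities
#'
#' Computes y2 = n_solute / (n_solute + n_CO2) with
#' n_solute = Cs * Vs / Ms and n_CO2 = Vl * rho / M_CO2, i.e. the moles of
#' drug collected from the sampling loop against the moles of CO2 the loop
#' held at the sampling condition.
#'
#' @param Cs solute concentration in the collection solvent, g/L.
#' @param Vs sample (collection) volume, L.
#' @param Vl sampling-loop volume, L.
#' @param rho CO2 density at the sampling condition, g/L.
#' @param Ms solute molar mass, g/mol.
#' @param Mco2 CO2 molar mass, g/mol.
#' @return Mole fraction y2 in [0, 1).
#' @examples
#' mole_fraction_from_sampling(0.05, 0.005, 6e-4, 769, 432.44, 44.01)
#' @export
mole_fraction_from_sampling <- function(Cs, Vs, Vl, rho, Ms, Mco2) {
  if (any(Cs < 0)) stop_domain("Cs must be >= 0")
  check_positive(Vs, "Vs"); check_positive(Vl, "Vl")
  check_positive(rho, "rho"); check_positive(Ms, "Ms")
  check_positive(Mco2, "Mco2")
  n_solute <- Cs * Vs / Ms
  n_co2 <- Vl * rho / Mco2
  n_solute / (n_solute + n_co2)
}

#' Equilibrium solubility in g per litre of CO2
#'
#' S = Cs * Vs / Vl: the mass of solute collected, referred back to the
#' volume of saturated fluid sampled.
#'
#' @inheritParams mole_fraction_from_sampling
#' @return Solubility in g/L.
#' @export
solubility_gL <- function(Cs, Vs, Vl) {
  if (any(Cs < 0)) stop_domain("Cs must be >= 0")
  check_positive(Vs, "Vs"); check_positive(Vl, "Vl")
  Cs * Vs / Vl
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat(sprintf("<solubility_dataset '%s': %d records, %d isotherm(s)>\n",
              attr(x, "label"), nrow(x), length(unique(x$temperature_K))))
  print(as.data.frame(x), ...)
  invisible(x)
}
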