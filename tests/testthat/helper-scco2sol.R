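## Shared helpers for the test suite.

## Report every expectation even when the study-value comparisons in the
## acceptance file disagree with the re-computed optima.
options(testthat.progress.max_fails = 1000L)

## Fast fitting configuration: the analytic start plus a handful of
## Latin-hypercube starts is enough for the well-conditioned unit-test
## problems; acceptance checks use the default 64 starts.
quick_config <- function(objective = "aard", n_starts = 8, seed = 1) {
  fit_config(objective = objective, n_starts = n_starts, seed = seed)
}

table2 <- function() load_dataset("builtin:table2")

## Write a throwaway dataset CSV and return its path.
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

## A small, well-behaved two-isotherm frame for validation tests.
tiny_frame <- function() {
  data.frame(
    temperature_K = c(308, 308, 308, 318, 318, 318),
    pressure_MPa = c(12, 18, 24, 12, 18, 24),
    density_kg_m3 = c(769, 849, 896, 661, 791, 851),
    mole_fraction = c(6.48e-6, 9.21e-6, 1.239e-5, 5.48e-6, 9.9e-6, 1.436e-5)
  )
}
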