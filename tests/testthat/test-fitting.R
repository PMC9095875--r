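test_that("noise-free synthetic Chrastil data is recovered exactly", {
  theta <- c(kappa = 7, E0 = -28, E1 = -7000)
  ds <- synthetic_dataset("chrastil", theta, noise_level = 0, seed = 3)
  f <- fit_model(ds, "chrastil", quick_config(n_starts = 4))
  expect_lt(f$objective_value, 1e-6)          # AARD% essentially zero
  expect_equal(f$parameters[["kappa"]], 7, tolerance = 1e-4)
  expect_equal(f$parameters[["E1"]], -7000, tolerance = 1e-3)
  expect_true(f$converged)
})

test_that("fitting is deterministic given the configuration", {
  d <- table2()
  cfg <- quick_config(n_starts = 6, seed = 42)
  f1 <- fit_model(d, "bartle", cfg)
  f2 <- fit_model(d, "bartle", cfg)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$objective_value, f2$objective_value)
})

test_that("more starts never worsen the objective (shared first start)", {
  d <- table2()
  f1 <- fit_model(d, "alwi_garlapati", quick_config(n_starts = 1))
  f16 <- fit_model(d, "alwi_garlapati", quick_config(n_starts = 16))
  expect_lte(f16$objective_value, f1$objective_value + 1e-12)
})

test_that("the optimizer honours the configured objective", {
  d <- table2()
  fa <- fit_model(d, "chrastil", quick_config("aard"))
  fs <- fit_model(d, "chrastil", quick_config("sse_y"))
  expect_lte(fa$metrics$aard_percent, fs$metrics$aard_percent + 1e-8)
  expect_lte(fs$metrics$sse, fa$metrics$sse + 1e-20)
  fl <- fit_model(d, "chrastil", quick_config("sse_log_y"))
  expect_true(is.finite(fl$objective_value))
})

test_that("fit results carry complete metrics and diagnostics", {
  d <- table2()
  f <- fit_model(d, "sodeifian", quick_config(n_starts = 4))
  expect_s3_class(f, "scco2_fit")
  expect_length(f$predictions, nrow(d))
  expect_gte(f$objective_value, 0)
  expect_equal(f$metrics$n, 24)
  expect_equal(f$metrics$q, 6)
  expect_equal(f$metrics$rmse^2 * f$metrics$n, f$metrics$sse,
               tolerance = 1e-12)
  expect_true(f$n_starts_converged >= 1)
  expect_output(print(f), "scco2_fit sodeifian")
})

test_that("MT is fitted by exact transformed-space least squares", {
  d <- table2()
  f <- fit_model(d, "mt", quick_config())
  k <- substance_constants()
  z <- d$temperature_K * log(d$mole_fraction * d$pressure_MPa *
                               k$mt_pressure_scale)
  ols <- stats::lm(z ~ d$density_kg_m3 + d$temperature_K)
  expect_equal(unname(f$parameters), unname(stats::coef(ols)),
               tolerance = 1e-10)
  expect_true(f$converged)
  expect_equal(f$n_starts, 1L)
})

test_that("per-isotherm fitting splits, errors and aggregates correctly", {
  d <- table2()
  fl <- fit_per_isotherm(d, "chrastil", quick_config(n_starts = 4))
  expect_length(fl, 4)
  expect_equal(as.numeric(names(fl)), c(308, 318, 328, 338))
  expect_equal(fl[["318"]]$isotherm_temperature, 318)
  expect_equal(fl[["318"]]$scope, "per_isotherm")

  single <- solubility_dataset(as.data.frame(d[d$temperature_K == 308, ]))
  fl1 <- fit_per_isotherm(single, "chrastil", quick_config(n_starts = 4))
  expect_length(fl1, 1)

  two_pts <- solubility_dataset(as.data.frame(d[c(1, 2), ]))
  expect_error(fit_per_isotherm(two_pts, "chrastil", quick_config()),
               "isotherm 308")
})

test_that("per-isotherm optima are at least as good as the global fit on each isotherm", {
  d <- table2()
  cfg <- quick_config(n_starts = 8)
  fg <- fit_model(d, "new_model", cfg)
  fl <- fit_per_isotherm(d, "new_model", cfg)
  per_iso_aard <- vapply(fl, function(f) f$metrics$aard_percent, numeric(1))
  expect_lte(mean(per_iso_aard), fg$metrics$aard_percent + 0.05)
})

test_that("rescaling the critical density is compensated by the fitted parameters", {
  d <- table2()
  cfg <- fit_config(objective = "aard", n_starts = 1, seed = 1)
  k1 <- substance_constants()
  k2 <- substance_constants(solvent_rhoc = 2 * k1$solvent_rhoc)
  f1 <- fit_model(d, "alwi_garlapati", cfg, k1)
  f2 <- fit_model(d, "alwi_garlapati", cfg, k2)
  expect_equal(f2$metrics$aard_percent, f1$metrics$aard_percent,
               tolerance = 1e-6)
  expect_equal(f2$parameters[["A2"]], 2 * f1$parameters[["A2"]],
               tolerance = 1e-3)
})

test_that("degenerate inputs raise informative errors", {
  d <- table2()
  expect_error(fit_model(d, "unknown_model"), "unknown model")
  three <- solubility_dataset(as.data.frame(d[1:3, ]))
  expect_error(fit_model(three, "sodeifian", quick_config()),
               "fewer records")
  cfg <- quick_config()
  expect_error(fit_config(n_starts = 0), "n_starts")
  expect_error(fit_config(tolerance = 0), "tolerance")
})
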