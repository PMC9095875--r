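k0 <- substance_constants()

test_that("fugacity ratio is exactly 1 at the melting point and matches direct arithmetic", {
  expect_equal(fugacity_ratio(412, 412, dCp = 137), 1)
  expect_equal(fugacity_ratio(412, 412, dHm = 2.5e4, dCp = -50), 1)
  # frozen: exp(6.54 * (1 - 308/412)) and exp(6.54 * (1 - 412/308))
  expect_equal(fugacity_ratio(308, 412, dCp = 0, melting_term = "printed"),
               5.21153160373, tolerance = 1e-9)
  expect_equal(fugacity_ratio(308, 412, dCp = 0, melting_term = "textual"),
               0.109886013836, tolerance = 1e-9)
  # full form with a known melting enthalpy, frozen by direct arithmetic:
  # exp(25000/(8.314*308)*(308/412 - 1)) for dCp = 0
  expect_equal(fugacity_ratio(308, 412, dHm = 2.5e4, dCp = 0),
               exp(2.5e4 / (8.314 * 308) * (308 / 412 - 1)),
               tolerance = 1e-12)
  expect_error(fugacity_ratio(-1, 412, dCp = 0), "temperature")
})

test_that("regular-solution activity coefficient has the exact symmetry limits", {
  expect_equal(gamma_infinity(308, 769, 2.8202e-4, 0, 0), 1)
  # a11 = a22 = a with v2*rho = 1: exponent (a + a - 2a)/RT = 0
  expect_equal(gamma_infinity(320, 769, 1 / 769, 5000, 5000), 1)
  # frozen high-precision evaluation at the 308 K record
  expect_equal(gamma_infinity(308, 769, 2.8202e-4, 1.0939e6, 1.3423e3),
               2.57025806361e34, tolerance = 1e-8)
  expect_gt(gamma_infinity(310, 500, 2.8202e-4, 1e5, 1e4), 0)
  expect_error(gamma_infinity(308, 769, 2.8202e-4, -1, 10), "non-negative")
})

test_that("SLE model composes fugacity ratio and activity coefficient", {
  # at T = Tm with zero interaction constants both factors are unity
  expect_equal(predict_new_model(412, 769, c(dCp = 0, a11 = 0, a22 = 0), k0), 1)
  # with a11 = a22 = 0 the prediction is the bare fugacity ratio
  expect_equal(predict_new_model(308, 769, c(dCp = 0, a11 = 0, a22 = 0), k0),
               fugacity_ratio(308, 412, dCp = 0))
  p <- c(dCp = 300, a11 = 2e4, a22 = 6e4)
  expect_equal(predict_new_model(308, 769, p, k0),
               fugacity_ratio(308, 412, dCp = 300) /
                 gamma_infinity(308, 769, 2.8202e-4, 2e4, 6e4))
})

test_that("Alwi-Garlapati model has the stated closed-form limits", {
  Tr <- 308 / k0$solvent_Tc; rr <- 769 / k0$solvent_rhoc
  expect_equal(predict_alwi_garlapati(308, 769, c(A0 = 0, A1 = 0, A2 = 0), k0),
               1 / (rr * Tr))
  # T = Tc, rho = rhoc, A0 = -A1, A2 = 0: the exponent cancels
  expect_equal(
    predict_alwi_garlapati(k0$solvent_Tc, k0$solvent_rhoc,
                           c(A0 = 7.5, A1 = -7.5, A2 = 0), k0), 1)
})

test_that("Sodeifian and Reddy-Garlapati empirical forms evaluate exactly", {
  expect_equal(predict_sodeifian(308, 12, 769, setNames(rep(0, 6), paste0("B", 0:5))), 1)
  # B2 = 1, rho*T = 1: ln(1) = 0
  expect_equal(predict_sodeifian(0.5, 12, 2, c(B0 = 0, B1 = 0, B2 = 1,
                                               B3 = 0, B4 = 0, B5 = 0)), 1)
  Tr <- 308 / k0$solvent_Tc
  expect_equal(predict_reddy_garlapati(308, 12, c(D0 = 1, D1 = 0, D2 = 0,
                                                  D3 = 0, D4 = 0, D5 = 0), k0),
               Tr^2)
  expect_equal(predict_reddy_garlapati(308, 12,
                                       setNames(rep(0, 6), paste0("D", 0:5)),
                                       k0), 0)
})

test_that("Chrastil family has the stated limits and saturating form", {
  expect_equal(predict_chrastil(308, 769, c(kappa = 1, E0 = 0, E1 = 0)), 0.5)
  expect_lt(predict_chrastil(308, 769, c(kappa = 1, E0 = -60, E1 = 0)), 1e-20)
  y <- predict_chrastil(308, 769, c(kappa = 7.3712, E0 = -29.074, E1 = -7147.4))
  expect_true(is.finite(y) && y > 0 && y < 1)
  expect_equal(predict_r_chrastil(308, 769, c(kappa_p = 1, F0 = 0, F1 = 0), k0), 1)
})

test_that("reformulated Chrastil scales as an exact power law in the standard-state fugacity", {
  p <- c(kappa_p = 6.5, F0 = -50, F1 = -4800)
  c_scale <- 3.7
  k2 <- substance_constants(rchrastil_f_std = k0$rchrastil_f_std * c_scale)
  y1 <- predict_r_chrastil(318, 744, p, k0)
  y2 <- predict_r_chrastil(318, 744, p, k2)
  expect_equal(y2, y1 * c_scale^(1 - p[["kappa_p"]]), tolerance = 1e-12)
})

test_that("Bartle model limits and structure hold", {
  expect_equal(predict_bartle(308, 12, 700, c(G0 = 0, G1 = 0, G2 = 0), k0),
               0.1 / 12)
  # G2 = 0 removes the density dependence
  ya <- predict_bartle(308, 12, 500, c(G0 = 5, G1 = -2000, G2 = 0), k0)
  yb <- predict_bartle(308, 12, 900, c(G0 = 5, G1 = -2000, G2 = 0), k0)
  expect_identical(ya, yb)
  expect_error(predict_bartle(308, 0, 700, c(G0 = 0, G1 = 0, G2 = 0), k0),
               "pressure")
})

test_that("MT model inverts its defining line and is monotone in density", {
  # zero parameters: y2 = 1/P in the model's bar convention
  expect_equal(predict_mt(308, 12, 769, c(H0 = 0, H1 = 0, H2 = 0), k0),
               1 / 120)
  rho <- seq(400, 900, 50)
  y <- predict_mt(308, 12, rho, c(H0 = -13000, H1 = 4.3, H2 = 29), k0)
  expect_true(all(diff(y) > 0))
  # round trip: the transform of a prediction recovers the line exactly
  p <- c(H0 = -13000, H1 = 4.3, H2 = 29)
  yy <- predict_mt(318, 21, 824, p, k0)
  expect_equal(318 * log(yy * 21 * k0$mt_pressure_scale) - p[["H2"]] * 318,
               p[["H0"]] + p[["H1"]] * 824, tolerance = 1e-9)
})

test_that("convention constants are absorbed exactly by compensated parameters", {
  d <- table2()
  # Alwi-Garlapati: doubling rhoc halves rho_r; A2 -> 2 A2, A0 -> A0 - ln 2
  p <- c(A0 = 2.0, A1 = -19.8, A2 = 3.6)
  k2 <- substance_constants(solvent_rhoc = 2 * k0$solvent_rhoc)
  p2 <- c(A0 = p[["A0"]] - log(2), A1 = p[["A1"]], A2 = 2 * p[["A2"]])
  expect_equal(predict_solubility("alwi_garlapati", d, p2, k2),
               predict_solubility("alwi_garlapati", d, p, k0),
               tolerance = 1e-12)
  # Bartle: moving Pref and rhoref is compensated through G0
  pb <- c(G0 = 21.4, G1 = -9130, G2 = 0.0125)
  k3 <- substance_constants(bartle_Pref = 0.25, bartle_rhoref = 600)
  pb2 <- c(G0 = pb[["G0"]] + log(0.1 / 0.25) + pb[["G2"]] * (600 - 700),
           G1 = pb[["G1"]], G2 = pb[["G2"]])
  expect_equal(predict_solubility("bartle", d, pb2, k3),
               predict_solubility("bartle", d, pb, k0), tolerance = 1e-12)
  # MT: the pressure unit is absorbed by H2
  pm <- c(H0 = -10758, H1 = 3.12, H2 = 19.9)
  k4 <- substance_constants(mt_pressure_scale = 1)    # MPa instead of bar
  pm2 <- c(H0 = pm[["H0"]], H1 = pm[["H1"]], H2 = pm[["H2"]] - log(10))
  expect_equal(predict_solubility("mt", d, pm2, k4),
               predict_solubility("mt", d, pm, k0), tolerance = 1e-12)
  # Chrastil: a density-unit change c is compensated by E0 -= (kappa-1) ln c
  pc <- c(kappa = 7.47, E0 = -33.3, E1 = -6777)
  pc2 <- c(kappa = pc[["kappa"]], E0 = pc[["E0"]] - (pc[["kappa"]] - 1) * log(2),
           E1 = pc[["E1"]])
  expect_equal(
    predict_chrastil(d$temperature_K, 2 * d$density_kg_m3, pc2),
    predict_chrastil(d$temperature_K, d$density_kg_m3, pc),
    tolerance = 1e-12)
})

test_that("predictions stay finite and positive across the fixture grid", {
  d <- table2()
  sets <- list(
    new_model = c(dCp = 300, a11 = 2e4, a22 = 6e4),
    alwi_garlapati = c(A0 = 2.0, A1 = -19.8, A2 = 3.6),
    sodeifian = c(B0 = -12.7, B1 = -2.9e-3, B2 = 3.14, B3 = 1.37e-3,
                  B4 = -0.0214, B5 = -2201),
    reddy_garlapati = c(D0 = -1.25e-3, D1 = 5.6e-6, D2 = 2.8e-4,
                        D3 = 1.38e-3, D4 = -5.7e-5, D5 = -2.6e-4),
    chrastil = c(kappa = 7.47, E0 = -33.3, E1 = -6777),
    r_chrastil = c(kappa_p = 6.7, F0 = -33.0, F1 = -4318),
    bartle = c(G0 = 21.4, G1 = -9130, G2 = 0.0125),
    mt = c(H0 = -10758, H1 = 3.12, H2 = 19.9)
  )
  for (id in names(sets)) {
    y <- predict_solubility(id, d, sets[[id]], k0)
    expect_true(all(is.finite(y)), info = id)
    if (id != "reddy_garlapati") expect_true(all(y > 0), info = id)
  }
})

test_that("overflow in model exponents saturates with a warning instead of erroring", {
  expect_warning(y <- predict_chrastil(308, 769, c(kappa = 200, E0 = 0, E1 = 0)),
                 "clipped")
  expect_true(is.finite(y) && y <= 1)
  expect_warning(y2 <- predict_sodeifian(308, 12, 769,
                                         c(B0 = 1e5, B1 = 0, B2 = 0,
                                           B3 = 0, B4 = 0, B5 = 0)),
                 "clipped")
  expect_true(is.finite(y2))
})

test_that("the registry exposes eight models with the published parameter counts", {
  expect_setequal(model_ids(),
                  c("new_model", "alwi_garlapati", "sodeifian",
                    "reddy_garlapati", "chrastil", "r_chrastil", "bartle", "mt"))
  counts <- vapply(model_ids(), function(id) model_info(id)$parameter_count,
                   integer(1))
  expect_equal(unname(counts[c("new_model", "alwi_garlapati", "sodeifian",
                               "reddy_garlapati", "chrastil", "r_chrastil",
                               "bartle", "mt")]),
               c(3L, 3L, 6L, 6L, 3L, 3L, 3L, 3L))
  for (id in model_ids()) {
    m <- model_info(id)
    expect_equal(length(m$parameter_names), m$parameter_count, info = id)
    expect_true(all(m$lower < m$upper), info = id)
  }
  expect_error(model_info("nope"), "unknown model")
  # parameter vectors are accepted named in any order, or unnamed in order
  d <- table2()
  expect_equal(
    predict_solubility("chrastil", d, c(E1 = -6777, kappa = 7.47, E0 = -33.3)),
    predict_solubility("chrastil", d, c(7.47, -33.3, -6777)))
  expect_error(predict_solubility("chrastil", d, c(1, 2)), "expected 3")
})
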