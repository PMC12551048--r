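test_that("presets reproduce the fitted-model equations at the centering values", {
  for (f in c("ecmps", "mmf")) {
    m <- mpa_model(f)
    centers <- vapply(m$effects$Cl, `[[`, numeric(1), "center")
    names(centers) <- vapply(m$effects$Cl, `[[`, character(1), "name")
    p <- individual_params(m, list(PTP = centers[["PTP"]], TDD = centers[["TDD"]]))
    expect_identical(p$ka, m$kapop)
    expect_identical(p$V, m$Vpop)
    expect_equal(p$Cl, m$Clpop, tolerance = 1e-15)
  }
})

test_that("covariate effects are log-linear and monotone in TDD and PTP", {
  m <- mpa_model("ecmps")
  base <- individual_params(m, list(TDD = 1500, PTP = 67))$Cl
  doubled <- individual_params(m, list(TDD = 3000, PTP = 67))$Cl
  expect_equal(doubled, base * 2^0.77, tolerance = 1e-12)
  expect_equal(individual_params(m, list(TDD = 1500, PTP = 134))$Cl,
               base * 2^0.16, tolerance = 1e-12)
  tdd_grid <- c(360, 720, 1080, 1440, 2880)
  cl_grid <- vapply(tdd_grid, function(d) {
    individual_params(m, list(TDD = d, PTP = 67))$Cl
  }, numeric(1))
  expect_true(all(diff(cl_grid) > 0))
})

test_that("random effects shift parameters on the log scale", {
  m <- mpa_model("ecmps")
  p <- individual_params(m, list(TDD = 1500, PTP = 67),
                         eta = c(ka = 0.1, V = -0.2, Cl = 0.3),
                         kappa = c(ka = 0, V = 0, Cl = 0.1))
  expect_equal(p$ka, 0.18 * exp(0.1))
  expect_equal(p$V, 192.42 * exp(-0.2))
  expect_equal(p$Cl, 9.3 * exp(0.4), tolerance = 1e-12)
})

test_that("missing or non-positive covariates raise named errors", {
  m <- mpa_model("ecmps")
  expect_error(individual_params(m, list(TDD = 1500)), "PTP")
  expect_error(individual_params(m, list(TDD = -10, PTP = 67)), "TDD")
})

test_that("MMF doses convert with the 0.72 factor", {
  expect_identical(convert_mmf_dose(0), 0)
  expect_equal(convert_mmf_dose(1000), 720)
  expect_equal(convert_mmf_dose(1), 0.72)
  expect_error(convert_mmf_dose(-1), ">= 0")
})

test_that("sampled random effects match their generating distribution", {
  spec <- random_effect_spec(omega = c(ka = 0, V = 0, Cl = 0.27),
                             gamma = c(ka = 0, V = 0, Cl = 0.31))
  set.seed(42)
  eff <- sample_effects(spec, 1e5, 2)
  expect_identical(unname(eff$eta[, "ka"]), rep(0, 1e5))
  expect_equal(sd(eff$eta[, "Cl"]), 0.27, tolerance = 0.01)
  expect_equal(sd(eff$kappa[, 1, "Cl"]), 0.31, tolerance = 0.01)
  # lognormal median: median of exp(eta) Clpop is Clpop
  expect_equal(median(9.3 * exp(eff$eta[, "Cl"])), 9.3, tolerance = 0.01)
  expect_error(sample_effects(spec, -1), ">= 1")
})

test_that("residual-error SD follows the variance decomposition", {
  expect_equal(obs_sd(1, error_model("additive", a = 0.04)), 0.04)
  expect_equal(obs_sd(0, error_model("combined", a = 0.04, b = 0.06)), 0.04)
  expect_equal(obs_sd(2, error_model("proportional", b = 0.06)), 0.12)
  expect_equal(obs_sd(2, error_model("combined", a = 0.04, b = 0.06)),
               sqrt(0.04^2 + 0.12^2))
  set.seed(7)
  draws <- observe(rep(2, 1e5), error_model("combined", a = 0.04, b = 0.06))
  expect_equal(sd(draws), sqrt(0.04^2 + 0.12^2), tolerance = 0.01)
  expect_equal(mean(draws), 2, tolerance = 0.005)
})

test_that("observations are floored at a small positive concentration", {
  set.seed(1)
  draws <- observe(rep(0.001, 1000), error_model("additive", a = 1))
  expect_true(all(draws >= 1e-6))
  expect_error(observe(-1, error_model("additive", a = 1)), ">= 0")
})

test_that("error-model validation enforces component positivity", {
  expect_error(error_model("additive", a = 0), "a > 0")
  expect_error(error_model("proportional", b = 0), "b > 0")
  expect_error(error_model("combined", a = 0.1, b = 0), "b > 0")
  expect_error(error_model("additive", a = -1), ">= 0")
})

test_that("preset loader validates completeness", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(formulation = "x", kapop = 1), path, auto_unbox = TRUE)
  expect_error(load_model_preset(path), "incomplete")
  expect_error(load_model_preset("no-such-file.json"), "not found")
})
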