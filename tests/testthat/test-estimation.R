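# small single-formulation generating model used across estimation tests
est_truth <- function() {
  m <- mpa_model("ecmps")
  m$random <- random_effect_spec(omega = c(ka = 0.2, V = 0.3, Cl = 0.27))
  m
}

small_rich_data <- function(n = 30, seed = 4, truth = est_truth()) {
  set.seed(seed)
  generate_rich_cohort(n, times = c(1, 3, 6, 12), truth = truth)$data
}

test_that("MAP estimation honours the prior in its limits", {
  # omega = 0: no random effect, eta is exactly zero
  m <- noise_free_model(mpa_model("ecmps"))
  d <- data.frame(ID = 1, OCC = 1, DV = 3, AMT = 720, II = 12, TAD = 12,
                  TDD = 1440, PTP = 67)
  res <- map_individual(m, d)
  expect_identical(unname(res$eta), c(0, 0, 0))
  expect_error(map_individual(m, d[0, ]), "no usable observations")
})

test_that("MAP recovers a known clearance effect from one clean trough", {
  m <- mpa_model("ecmps")
  m$random <- random_effect_spec(omega = c(ka = 0, V = 0, Cl = 0.27))
  m$error <- error_model("additive", a = 1e-6)
  eta_true <- 0.3
  cov <- list(TDD = 1440, PTP = 67)
  p <- individual_params(m, cov, eta = c(ka = 0, V = 0, Cl = eta_true))
  d <- data.frame(ID = 1, OCC = 1, DV = trough_ss(p, regimen(720, 12)),
                  AMT = 720, II = 12, TAD = 12, TDD = 1440, PTP = 67)
  res <- map_individual(m, d)
  # oracle: invert the monotone trough(eta_Cl) mapping directly
  f <- function(e) {
    pe <- individual_params(m, cov, eta = c(ka = 0, V = 0, Cl = e))
    trough_ss(pe, regimen(720, 12)) - d$DV
  }
  oracle <- uniroot(f, c(-2, 2), tol = 1e-12)$root
  expect_equal(res$eta[["Cl"]], oracle, tolerance = 1e-3)
  expect_equal(oracle, eta_true, tolerance = 1e-6)
  # the optimiser improved on the eta = 0 start
  null_obj <- map_individual(noise_free_model(m), d)$objective
  expect_true(is.finite(res$objective))
})

test_that("the marginal likelihood is lowest at the generating parameters", {
  truth <- est_truth()
  truth$random <- random_effect_spec()                        # no IIV/IOV
  truth$error <- error_model("combined", a = 0.02, b = 0.03)  # light noise
  d <- small_rich_data(20, seed = 6, truth = truth)
  ll0 <- loglik_population(d, truth)
  set.seed(10)
  for (k in 1:20) {
    pert <- truth
    fac <- exp(runif(1, log(1.15), log(1.6))) ^ sample(c(-1, 1), 1)
    which_par <- sample(c("Clpop", "Vpop", "kapop"), 1)
    pert[[which_par]] <- pert[[which_par]] * fac
    expect_gt(loglik_population(d, pert), ll0)
  }
})

test_that("a small rich-design fit recovers clearance and its IIV", {
  d <- small_rich_data(30, seed = 4)
  start <- est_truth()
  start$Clpop <- 7
  start$random$omega["Cl"] <- 0.15
  fit <- fit_population(d, start, free = c("Clpop", "omega_Cl"))
  expect_equal(fit$estimates[["Clpop"]], 9.3, tolerance = 0.15)
  expect_equal(fit$estimates[["omega_Cl"]], 0.27, tolerance = 0.35)
  # information criteria arithmetic is exact
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_free)
  expect_equal(fit$bic, fit$ofv + fit$n_free * log(fit$n_obs))
  expect_equal(unname(fit$rse), unname(100 * fit$se / abs(fit$estimates)))
  # EBEs centred near zero at a consistent model
  expect_lt(abs(mean(fit$ebe[, "Cl"])), 0.15)
})

test_that("the MMF-formulation model is recoverable too", {
  truth <- mpa_model("mmf")
  truth$random <- random_effect_spec(omega = c(ka = 0.27, V = 0.09, Cl = 0.32))
  set.seed(14)
  rc <- generate_rich_cohort(30, times = c(1, 3, 6, 12), truth = truth)
  start <- truth
  start$Clpop <- 7
  start$random$omega["Cl"] <- 0.15
  fit <- fit_population(rc$data, start, free = c("Clpop", "omega_Cl", "b"),
                        se = FALSE)
  expect_equal(fit$estimates[["Clpop"]], 9.3, tolerance = 0.15)
  expect_equal(fit$estimates[["omega_Cl"]], 0.32, tolerance = 0.35)
})

test_that("information criteria follow their defining formulas", {
  # for p = 5 free parameters, N = 209 observations, -2LL = 100:
  expect_equal(100 + 2 * 5, 110)
  f <- structure(list(ofv = 100, n_free = 5, n_obs = 209), class = "mpa_fit")
  expect_equal(f$ofv + 2 * f$n_free, 110)
  expect_equal(f$ofv + f$n_free * log(f$n_obs), 100 + 5 * log(209))
})

test_that("stepwise release never increases the objective", {
  d <- small_rich_data(25, seed = 12)
  start <- est_truth()
  start$Clpop <- 7
  fits <- fit_stepwise(d, start,
                       stages = list(c("Clpop", "omega_Cl"),
                                     c("Clpop", "omega_Cl", "kapop", "omega_ka")),
                       se = FALSE)
  expect_equal(length(fits), 2)
  expect_lte(fits[[2]]$ofv, fits[[1]]$ofv + 1e-6)
})

test_that("unidentifiable one-observation designs trigger the stepwise warning", {
  m <- est_truth()
  d <- data.frame(ID = 1:5, OCC = 1, DV = c(2, 3, 2.5, 4, 3.2),
                  AMT = 720, II = 12, TAD = 12, TDD = 1440, PTP = 67)
  expect_warning(
    fit_population(d, m, free = c("kapop", "Vpop", "Clpop"), se = FALSE,
                   control = list(iter.max = 2, rel.tol = 1e-3)),
    "stepwise")
})

test_that("covariate selection keeps a real effect and drops pure noise", {
  truth <- est_truth()
  set.seed(31)
  rc <- generate_rich_cohort(40, times = c(1, 4, 12), truth = truth)
  d <- rc$data
  d$NOISE <- rep(exp(rnorm(40, 0, 0.5)), each = 3)
  base <- truth
  base$effects <- list()       # candidates enter from scratch
  base$Clpop <- 7
  base$random$omega["Cl"] <- 0.4
  res <- covariate_search(d, base, candidates = c("TDD", "NOISE"),
                          free_base = c("Clpop", "omega_Cl"))
  kept <- vapply(res$model$effects$Cl, `[[`, character(1), "name")
  expect_true("TDD" %in% kept)
  expect_false("NOISE" %in% kept)
  expect_true(all(c("step", "covariate", "p", "decision") %in% names(res$log)))
  # empty candidate set returns the base model unchanged
  res0 <- covariate_search(d, base, candidates = character(0),
                           free_base = c("Clpop", "omega_Cl"))
  expect_identical(res0$model$effects, base$effects)
})
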