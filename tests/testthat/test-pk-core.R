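p_ecmps <- pk_params(ka = 0.18, V = 192.42, Cl = 9.3)

test_that("parameter and regimen validation rejects non-physical input", {
  expect_error(pk_params(-0.1, 192, 9.3), "ka")
  expect_error(pk_params(0.18, 0, 9.3), "V")
  expect_error(pk_params(0.18, 192, NA), "Cl")
  expect_error(regimen(-10, 12), "dose")
  expect_error(regimen(360, 0), "interval")
  expect_error(regimen(360, 12, 0), "n_doses")
  expect_error(conc_single_dose(p_ecmps, 720, -1), "non-negative")
})

test_that("single-dose profile has the right boundary behaviour", {
  expect_identical(conc_single_dose(p_ecmps, 720, 0), 0)
  expect_identical(conc_single_dose(p_ecmps, 0, c(1, 5, 20)), c(0, 0, 0))
  # dose proportionality to machine precision
  t <- c(0.5, 2, 6, 12, 24)
  expect_equal(conc_single_dose(p_ecmps, 1440, t),
               2 * conc_single_dose(p_ecmps, 720, t), tolerance = 1e-14)
})

test_that("closed form matches the ODE oracle across the parameter grid", {
  skip_if_not_installed("deSolve")
  t_eval <- c(1, 4, 12, 36)
  for (ka in c(0.05, 0.18, 1)) {
    for (V in c(50, 192.42, 400)) {
      for (Cl in c(1, 9.3, 20)) {
        p <- pk_params(ka, V, Cl)
        ora <- ode_oracle(p, 0, 720, t_eval)
        expect_equal(conc_single_dose(p, 720, t_eval), ora, tolerance = 1e-6)
      }
    }
  }
})

test_that("multiple-dose superposition matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  r <- regimen(720, 12, 14)
  t_eval <- c(13, 60.5, 167.99)
  ora <- ode_oracle(p_ecmps, seq(0, by = 12, length.out = 14), 720, t_eval)
  expect_equal(conc_multi_dose(p_ecmps, r, t_eval), ora, tolerance = 1e-6)
  # degenerate single-dose case
  expect_equal(conc_multi_dose(p_ecmps, regimen(720, 12, 1), c(3, 30)),
               conc_single_dose(p_ecmps, 720, c(3, 30)))
})

test_that("pre-dose concentrations accumulate monotonically to steady state", {
  pre_dose <- vapply(1:12, function(k) {
    conc_multi_dose(p_ecmps, regimen(720, 12, k), k * 12 - 1e-9)
  }, numeric(1))
  expect_true(all(diff(pre_dose) > 0))
  # and converge towards the steady-state trough
  expect_equal(pre_dose[12], trough_ss(p_ecmps, regimen(720, 12)),
               tolerance = 0.02)
})

test_that("flip-flop guard: general and limit formulas agree near ka = ke", {
  kel <- 9.3 / 192.42
  p_close <- pk_params(kel * (1 + 1e-6), 192.42, 9.3)
  p_limit <- pk_params(kel * (1 + 1e-12), 192.42, 9.3)  # limit branch
  t <- c(1, 6, 12, 48)
  expect_equal(conc_single_dose(p_close, 720, t),
               conc_single_dose(p_limit, 720, t), tolerance = 1e-6)
  # steady state too
  expect_equal(conc_ss(p_close, 720, 12, c(2, 12)),
               conc_ss(p_limit, 720, 12, c(2, 12)), tolerance = 1e-4)
})

test_that("steady-state AUC equals dose/Cl and behaves linearly", {
  r <- regimen(720, 12)
  expect_equal(auc_tau_ss(p_ecmps, r), 720 / 9.3)
  expect_equal(auc_tau_ss(p_ecmps, regimen(0, 12)), 0)
  p_half <- pk_params(0.18, 192.42, 9.3 / 2)
  expect_equal(auc_tau_ss(p_half, r), 2 * auc_tau_ss(p_ecmps, r))
  # trapezoid integration of the steady-state profile agrees within 0.5%
  tt <- seq(0, 12, by = 0.01)
  cc <- conc_ss(p_ecmps, 720, 12, tt)
  trap <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  expect_equal(trap, 720 / 9.3, tolerance = 0.005)
})

test_that("windowed steady-state AUC partitions the interval exactly", {
  expect_equal(auc_ss_window(p_ecmps, 720, 12, 0, 12), 720 / 9.3,
               tolerance = 1e-10)
  a1 <- auc_ss_window(p_ecmps, 720, 24, 0, 12)
  a2 <- auc_ss_window(p_ecmps, 720, 24, 12, 24)
  expect_equal(a1 + a2, 720 / 9.3, tolerance = 1e-10)
  expect_gt(a1, a2)  # absorption front-loads the interval
  expect_error(auc_ss_window(p_ecmps, 720, 12, 5, 3), "t1 < t2")
})

test_that("steady-state trough is consistent with long-run superposition", {
  r <- regimen(720, 12)
  t_half <- half_life(p_ecmps)
  n <- ceiling(10 * t_half / 12) + 1
  pre_dose <- conc_multi_dose(p_ecmps, regimen(720, 12, n), n * 12)
  expect_equal(trough_ss(p_ecmps, r), pre_dose, tolerance = 1e-3)
  expect_equal(trough_ss(p_ecmps, regimen(1440, 12)),
               2 * trough_ss(p_ecmps, r), tolerance = 1e-12)
})

test_that("half-life follows ln(2) V / Cl", {
  expect_equal(half_life(pk_params(1, 1, log(2))), 1)
  expect_equal(half_life(p_ecmps), log(2) * 192.42 / 9.3)
})
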