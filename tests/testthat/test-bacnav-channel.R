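# BacNav (h2SheP) gating kinetics: fitted curves, exact-relaxation updates,
# and the ohmic current law. Frozen expected values were computed from the
# fitted expressions with 30-digit arithmetic (mpmath).

test_that("time constants hit their depolarized asymptotes and fitted values", {
  # strongly depolarized: both denominator exponentials diverge (at +200 mV
  # the slower one still contributes ~2e-6 ms)
  expect_equal(tau_m(200), 1.66, tolerance = 1e-5)
  expect_equal(tau_h(100), 9.593, tolerance = 1e-9)
  # strongly hyperpolarized: the steep exponential would overflow a double
  # without the guard; the curve returns to its floor
  expect_equal(tau_m(-160), 1.66, tolerance = 1e-9)
  # interior fitted values
  expect_equal(tau_m(-10), 5.02866923743964, tolerance = 1e-12)
  expect_equal(tau_h(-80), 22.0450027012333, tolerance = 1e-12)
  expect_equal(tau_h(-27.15), 61.8672923750365, tolerance = 1e-12)
})

test_that("steady-state curves have the fitted midpoints, limits and monotonicity", {
  expect_identical(m_inf(-22.5), 0.5)
  expect_identical(h_inf(-77.05), 0.5)
  expect_equal(m_inf(100), 1, tolerance = 1e-12)
  expect_equal(m_inf(-33.3), 0.0180910216497237, tolerance = 1e-12)
  expect_equal(h_inf(-160), 0.999588813593522, tolerance = 1e-12)
  expect_equal(h_inf(-30), 0.0118677432770177, tolerance = 1e-12)
  v <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(m_inf(v)) > 0))
  expect_true(all(diff(h_inf(v)) < 0))
  expect_true(all(m_inf(v) > 0 & m_inf(v) < 1))
})

test_that("time constants stay finite and positive over an extreme voltage range", {
  v <- seq(-500, 500, by = 1)
  expect_true(all(is.finite(tau_m(v))) && all(tau_m(v) > 1.66 - 1e-12))
  expect_true(all(is.finite(tau_h(v))) && all(tau_h(v) > 9.593 - 1e-12))
  expect_error(tau_m(Inf), class = "bacnavsim_invalid_input")
  expect_error(h_inf(NA_real_), class = "bacnavsim_invalid_input")
})

test_that("gate updates relax exactly and match a fine-step Euler oracle", {
  g0 <- init_gates(-80)
  expect_equal(unname(g0["m"]), m_inf(-80))
  expect_equal(unname(g0["h"]), h_inf(-80))
  # identity and full-relaxation limits
  expect_identical(step_gates(g0, -20, 0), g0)
  g_inf <- step_gates(g0, -20, 1e6)
  expect_equal(unname(g_inf["m"]), m_inf(-20), tolerance = 1e-12)
  expect_equal(unname(g_inf["h"]), h_inf(-20), tolerance = 1e-12)
  expect_error(step_gates(g0, -20, -1), class = "bacnavsim_invalid_input")
  # explicit-Euler oracle over 10 ms at fixed Vm; the step is fine enough
  # that the oracle's own discretization error stays below the band
  vm <- -20
  dt <- 2e-5
  n <- 10 / dt
  m <- unname(g0["m"]); h <- unname(g0["h"])
  mi <- m_inf(vm); hi <- h_inf(vm); tm <- tau_m(vm); th <- tau_h(vm)
  for (i in seq_len(n)) {
    m <- m + dt * (mi - m) / tm
    h <- h + dt * (hi - h) / th
  }
  exact <- step_gates(g0, vm, 10)
  expect_lt(abs(m - unname(exact["m"])), 1e-6)
  expect_lt(abs(h - unname(exact["h"])), 1e-6)
})

test_that("gate trajectories are bounded in [0,1] for arbitrary voltage sequences", {
  set.seed(42)
  for (rep in 1:5) {
    g <- init_gates(runif(1, -120, 20))
    for (i in 1:200) {
      g <- step_gates(g, runif(1, -150, 80), runif(1, 0, 50))
      expect_true(all(g >= 0 & g <= 1))
    }
  }
})

test_that("the current law is ohmic, linear in expression, and gated", {
  p <- bacnav_params(x_level = 2, gbar_1x = 1, e_rev = 50)
  expect_identical(bacnav_current(0, c(m = 0.5, h = 0.5), p), -25)
  expect_identical(bacnav_current(0, c(m = 0, h = 0.9), p), 0)
  expect_identical(bacnav_current(50, c(m = 0.5, h = 0.5), p), 0)
  p1 <- bacnav_params(x_level = 1, gbar_1x = 3, e_rev = 60)
  p2 <- bacnav_params(x_level = 2, gbar_1x = 3, e_rev = 60)
  g <- c(m = 0.3, h = 0.7)
  expect_identical(bacnav_current(-10, g, p2), 2 * bacnav_current(-10, g, p1))
  expect_error(bacnav_params(x_level = -1), class = "bacnavsim_invalid_input")
  expect_error(bacnav_params(gbar_1x = 0), class = "bacnavsim_invalid_input")
})

test_that("the simulated BacNav current-voltage relation is inward and bell-shaped", {
  cell <- build_cell("human", x_level = 1, gbar_1x = 1)
  iv <- voltage_clamp(cell, holding = -80, steps = seq(-50, 50, 10),
                      step_ms = 120, current = "I_BacNav")
  expect_true(all(iv$peak[iv$step_mV >= -20] < 0))  # inward above threshold
  # negligible at far-subthreshold potentials, falling again toward E_Na
  expect_lt(abs(iv$peak[iv$step_mV == -50]), 0.5)
  expect_lt(abs(iv$peak[iv$step_mV == 50]), max(abs(iv$peak)))
  # magnitude is linear in the expression level
  cell2 <- build_cell("human", x_level = 2, gbar_1x = 1)
  iv2 <- voltage_clamp(cell2, holding = -80, steps = c(-20, 0),
                       step_ms = 120, current = "I_BacNav")
  expect_equal(iv2$peak,
               2 * iv$peak[iv$step_mV %in% c(-20, 0)], tolerance = 1e-6)
})
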