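# Transmural cable construction, Brugada parameterization, pseudo-ECG

test_that("transmural layers carry the printed per-cell parameters", {
  cab <- build_transmural_cable()
  expect_identical(cab$n_cells, 165L)
  expect_identical(sum(table(cab$layer)), 165L)
  expect_identical(as.integer(table(cab$layer)[c("endo", "mid", "epi")]),
                   c(60L, 45L, 60L))
  expect_identical(unname(cab$params["gto_max", 30]), 0)        # endocardial
  expect_identical(unname(cab$params["gto_max", 80]), 0.2125)   # midmyocardial
  expect_identical(unname(cab$params["gto_max", 150]), 0.25)    # epicardial
  expect_equal(unname(cab$params["gKs", 30] / cab$params["gKr", 30]), 11)
  expect_equal(unname(cab$params["gKs", 80] / cab$params["gKr", 80]), 4)
  expect_equal(unname(cab$params["gKs", 150] / cab$params["gKr", 150]), 35)
})

test_that("invalid layer specifications are rejected", {
  expect_error(transmural_spec(sizes = c(endo = 60, mid = 45, epi = 59)),
               class = "bacnavsim_invalid_spec")
  expect_error(transmural_spec(ito_max = c(endo = -1, mid = 0.2, epi = 0.25)),
               class = "bacnavsim_invalid_spec")
  expect_error(brugada_severity(inactivation_factor = 0.5, ito_mult = 3),
               class = "bacnavsim_invalid_input")
})

test_that("applying Brugada severities scales the printed parameters", {
  cab <- build_transmural_cable()
  same <- apply_brugada(cab, "none")
  expect_identical(same$params, cab$params)
  mild <- apply_brugada(cab, "mild")
  expect_identical(unname(mild$params["gto_max", 150]), 0.75)   # 0.25 x 3
  expect_identical(unname(mild$params["tauh_factor", 1]), 1.5)
  sev <- apply_brugada(cab, "severe")
  expect_identical(unname(sev$params["gto_max", 150]), 1.75)    # 0.25 x 7
  expect_identical(unname(sev$params["tauh_factor", 80]), 3.5)
})

test_that("pseudo-ECG vanishes for uniform fields and is linear in Vm", {
  x <- (1:100 - 0.5) * 0.01
  times <- seq(0, 10, 0.5)
  vm_u <- matrix(-20, length(times), 100)
  e <- pseudo_ecg(vm_u, times, x, electrode_x_cm = 3)
  expect_true(all(abs(e$phi) < 1e-15))
  set.seed(1)
  vm <- matrix(rnorm(length(times) * 100), length(times), 100)
  e1 <- pseudo_ecg(vm, times, x, electrode_x_cm = 3)
  e3 <- pseudo_ecg(3 * vm, times, x, electrode_x_cm = 3)
  expect_equal(e3$phi, 3 * e1$phi, tolerance = 1e-12)
  expect_error(pseudo_ecg(vm, times, x, electrode_x_cm = x[10]),
               class = "bacnavsim_singular_geometry")
})

test_that("pseudo-ECG matches fine quadrature of the lead-field integral", {
  # travelling Gaussian wave with closed-form spatial derivative, kept
  # inside the fiber for the whole window
  f <- analytic_fields(v_cm_s = 30, nx = 100, duration_ms = 15)$gaussian
  elec <- max(f$x_cm) + 0.5
  pkg <- pseudo_ecg(f$vm, f$times, f$x_cm, electrode_x_cm = elec)
  # oracle: analytic dVm/dx and d(1/r)/dx summed on a 20x finer grid
  k <- (10 * 1e-4)^2 / 4
  h <- 0.01 / 20
  xo <- seq(min(f$x_cm), max(f$x_cm), by = h)
  centers <- 0.25 + (30 / 1000) * f$times
  phi_oracle <- vapply(seq_along(f$times), function(i) {
    dvm <- 100 * exp(-(xo - centers[i])^2 / (2 * 0.05^2)) *
      (-(xo - centers[i]) / 0.05^2)
    dinvr <- 1 / (elec - xo)^2     # d/dx of 1/(elec - x), elec > x
    k * sum(-dvm * dinvr) * h
  }, numeric(1))
  scale <- max(abs(phi_oracle))
  expect_lt(max(abs(pkg$phi - phi_oracle)) / scale, 0.01)
})

test_that("the ECG deviation score is an L1 metric", {
  t1 <- seq(0, 100, 1)
  a <- list(times = t1, phi = sin(t1 / 10))
  b <- list(times = t1, phi = cos(t1 / 10))
  c3 <- list(times = t1, phi = sin(t1 / 8))
  expect_identical(ecg_deviation(a, a), 0)
  expect_equal(ecg_deviation(a, b), ecg_deviation(b, a))
  expect_lte(ecg_deviation(a, b),
             ecg_deviation(a, c3) + ecg_deviation(c3, b) + 1e-12)
  expect_error(ecg_deviation(a, list(times = t1 + 500, phi = t1)),
               class = "bacnavsim_alignment")
})

test_that("the dome rule classifies canonical AP shapes", {
  t <- seq(0, 300, 0.5)
  rest <- rep(-85, length(t))
  spike <- function(notch_v, dome_v) {
    v <- rest
    v[t >= 10 & t < 12] <- 35
    v[t >= 12 & t < 20] <- notch_v
    v[t >= 20 & t < 150] <- dome_v
    v
  }
  expect_true(has_dome(t, spike(-25, 5)))       # notch then dome
  expect_false(has_dome(t, spike(-60, -85)))    # collapse, no dome
  # notchless plateau is a dome
  v <- rest; v[t >= 10 & t < 160] <- -5
  expect_true(has_dome(t, v))
  # brief spike only
  v <- rest; v[t >= 10 & t < 14] <- 30
  expect_false(has_dome(t, v))
})
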