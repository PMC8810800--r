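# 1X expression calibration by peak-current matching

test_that("calibration matches peak currents within tolerance and is idempotent", {
  cell <- build_cell("human")
  rep <- calibrate_1x(cell, steps = seq(-40, 20, 10), step_ms = 100,
                      tol_pct = 0.1)
  expect_gt(rep$gbar_1x, 0)
  expect_lt(rep$mismatch_pct, 0.5)
  expect_equal(rep$peak_bacnav / rep$peak_ina_ref, 1, tolerance = 0.005)
  rep2 <- calibrate_1x(cell, steps = seq(-40, 20, 10), step_ms = 100,
                       tol_pct = 0.1)
  expect_equal(rep2$gbar_1x, rep$gbar_1x, tolerance = 0.002)
})

test_that("doubling the endogenous sodium conductance ~doubles gbar_1x", {
  r1 <- calibrate_1x(build_cell("human"), steps = c(-30, -20, -10, 0),
                     step_ms = 100)
  r2 <- calibrate_1x(build_cell("human", gNa_scale = 2),
                     steps = c(-30, -20, -10, 0), step_ms = 100)
  expect_equal(r2$gbar_1x / r1$gbar_1x, 2, tolerance = 0.05)
})

test_that("degenerate calibrations are signalled, loose tolerances reported honestly", {
  expect_error(calibrate_1x(build_cell("human", gNa_scale = 0)),
               class = "bacnavsim_calibration_undefined")
  rep <- calibrate_1x(build_cell("human"), steps = c(-20, 0), step_ms = 100,
                      tol_pct = 50)
  expect_lte(rep$mismatch_pct, 50)
  expect_identical(rep$mismatch_pct,
                   abs(rep$peak_bacnav - rep$peak_ina_ref) /
                     rep$peak_ina_ref * 100)
})

test_that("peak BacNav current under the protocol increases with conductance", {
  cell <- build_cell("human")
  peaks <- vapply(c(0.5, 2, 8), function(g) {
    probe <- cell
    probe$params[["g_bacnav"]] <- g
    iv <- voltage_clamp(probe, steps = c(-10, 0, 10), step_ms = 100,
                        current = "I_BacNav")
    max(abs(iv$peak))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
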