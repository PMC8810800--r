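# 1D monodomain cable: CV estimation, block detection, diffusion physics

test_that("measure_cv recovers an exact linear activation front", {
  act <- 0:99
  pos <- (0:99) * 0.01
  expect_equal(measure_cv(act, pos), 10)
})

test_that("degenerate and blocked fronts are signalled", {
  pos <- (0:99) * 0.01
  expect_error(measure_cv(rep(5, 100), pos),
               class = "bacnavsim_estimator_degenerate")
  act <- 0:99
  act[50] <- NA
  expect_error(measure_cv(act, pos), class = "bacnavsim_block")
  expect_error(measure_cv(act[1:4], pos[1:4], fit_window = 1:4),
               class = "bacnavsim_invalid_input")
})

test_that("regression recovers the true CV under activation-time jitter", {
  set.seed(7)
  v_true <- 44                           # cm/s
  pos <- (0:99) * 0.01
  for (i in 1:20) {
    act <- pos / (v_true / 1000) + runif(100, -0.05, 0.05)
    expect_equal(measure_cv(act, pos), v_true, tolerance = 0.02)
  }
})

test_that("detect_block reports the last activated position", {
  fake <- structure(list(
    thresh_time_ms = c(1, 2, 3, 4, 5, rep(NA, 5)),
    config = list(stim_cells = 1:3)), class = "cable_result")
  b <- detect_block(fake)
  expect_true(b$block)
  expect_identical(b$last_activated, 5L)
  fake$thresh_time_ms <- 1:10
  expect_false(detect_block(fake)$block)
})

test_that("pure diffusion with no-flux ends conserves the voltage integral", {
  # a toy cell with an enormous time scale has negligible membrane current,
  # leaving pure diffusion on the cable
  cell <- make_toy_model(list(t_scale = 1e12))
  n <- 60
  set.seed(3)
  st <- matrix(rep(cell$state, n), ncol = n)
  st[1, ] <- runif(n, -80, 20)
  pm <- matrix(cell$params, ncol = 1)
  r <- bacnavsim:::run_nodes("toy", pm, st, 0.01, 20,
                             coupling = 12.5,
                             nbrs = bacnavsim:::cable_neighbors(n))
  expect_equal(sum(r$state[1, ]), sum(st[1, ]), tolerance = 1e-10)
  # and the profile homogenizes
  expect_lt(diff(range(r$state[1, ])), diff(range(st[1, ])))
})

test_that("toy-model cable CV scales as the square root of diffusion", {
  D <- bacnavsim:::diffusion_coefficient(10, 0.4)
  cv1 <- toy_cable_cv(D)
  cv4 <- toy_cable_cv(4 * D)
  expect_equal(cv4 / cv1, 2, tolerance = 0.03)
})

test_that("sub-cell spatial refinement leaves the toy CV unchanged within 3%", {
  D <- bacnavsim:::diffusion_coefficient(10, 0.4)
  cv_coarse <- toy_cable_cv(D, dx = 0.01, dt = 0.004)
  cv_fine <- toy_cable_cv(D, dx = 0.005, dt = 0.001)
  expect_equal(cv_fine / cv_coarse, 1, tolerance = 0.03)
})

test_that("cable geometry validation rejects degenerate configurations", {
  expect_error(cable_config(n_cells = 5), class = "bacnavsim_invalid_input")
  expect_error(cable_config(radius_um = 0), class = "bacnavsim_invalid_input")
  # the printed geometry yields the monodomain diffusion coefficient a/(2 Ri Cm)
  expect_equal(bacnavsim:::diffusion_coefficient(10, 0.4), 1.25e-3)
})
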