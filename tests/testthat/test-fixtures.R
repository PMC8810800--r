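# Synthetic fixtures: toy model physics, analytic fields, canonical configs

test_that("toy parameter validation enforces the documented stable region", {
  expect_error(make_toy_model(list(a = 0.7)), class = "bacnavsim_invalid_input")
  expect_error(make_toy_model(list(k = 50)), class = "bacnavsim_invalid_input")
  expect_error(make_toy_model(list(nonsense = 1)), class = "bacnavsim_invalid_input")
  expect_s3_class(make_toy_model(), "bacnav_cell")
})

test_that("a subthreshold stimulus decays back to rest without an AP", {
  cell <- make_toy_model()
  st <- bacnavsim:::cell_state_matrix(cell)
  pm <- bacnavsim:::cell_param_matrix(cell)
  r <- bacnavsim:::run_nodes("toy", pm, st, 0.01, 200, stim_nodes = 1L,
                             stim_amp = 5, stim_dur = 1, stim_starts = 1,
                             record_dt = 1, record_nodes = 1L)
  expect_lt(max(r$vm[, 1]), -60)                     # never fires
  tail_v <- r$vm[r$times > 50, 1]
  expect_true(all(diff(tail_v) <= 1e-9))             # monotone return
  expect_equal(unname(r$state[1, 1]), -80, tolerance = 0.1)
})

test_that("toy APD matches a fine-step reference integration within 1%", {
  coarse <- simulate_ap(make_toy_model(dt = 0.01), record_dt = 0.1,
                        rate_hz = 1.5)
  fine <- simulate_ap(make_toy_model(dt = 1e-4), record_dt = 0.1,
                      rate_hz = 1.5)
  a <- attr(coarse, "features")$apd[["apd80"]]
  b <- attr(fine, "features")$apd[["apd80"]]
  expect_equal(a / b, 1, tolerance = 0.01)
})

test_that("analytic fields carry their constructed ground truth", {
  f <- analytic_fields(v_cm_s = 25, nx = 60, ny = 60)
  expect_identical(dim(f$planar), c(60L, 60L))
  # planar front: time grows linearly along x at 1/v
  expect_equal(f$planar[31, 5] - f$planar[30, 5], 0.01 / (25 / 1000))
  # circular front is radially symmetric around the corner
  expect_equal(f$circular[1, 10], f$circular[10, 1])
  # gaussian wave peaks where the moving center sits
  i <- 20
  xpk <- f$gaussian$x_cm[which.max(f$gaussian$vm[i, ])]
  expect_equal(xpk, 0.25 + 25 / 1000 * f$gaussian$times[i], tolerance = 0.011)
})

test_that("canonical configs cover the simulated experiments and round-trip", {
  cfgs <- canonical_configs()
  expect_gte(length(cfgs), 25)
  expect_identical(cfgs$tissue_random15$fraction, 0.15)
  expect_identical(cfgs$tissue_random15$dx_cm, 0.01)
  expect_identical(cfgs$tissue_vertical20$fraction, 0.2)
  expect_identical(cfgs$cable_human_gna100_x000$ri_kohm_cm, 0.4)
  expect_identical(cfgs$cable_human_gna100_x000$n_cells, 100)
  sev <- brugada_severity(cfgs$brugada_severe_x000$severity)
  expect_identical(sev$inactivation_factor, 3.5)
  expect_identical(sev$ito_mult, 7)
  # lossless round-trip through the shipped YAML representation
  for (nm in c("tissue_random15", "brugada_severe_x050",
               "cell_human_gna050_x100")) {
    path <- tempfile(fileext = ".yaml")
    write_config(cfgs[[nm]], path)
    expect_identical(read_config(path), validate_config(cfgs[[nm]]))
  }
  # the shipped copies match the in-code generator
  shipped <- system.file("configs", "tissue_random15.yaml",
                         package = "bacnavsim")
  expect_identical(read_config(shipped), validate_config(cfgs$tissue_random15))
})
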