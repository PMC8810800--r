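# Host ventricular myocyte models: baseline physiology, pacing bookkeeping,
# clamp protocols, and integrator consistency.

test_that("unknown species and bad parameters are rejected", {
  expect_error(build_cell("dog"), class = "bacnavsim_unsupported_model")
  expect_error(build_cell("human", conductances = list(nonsense = 2)),
               class = "bacnavsim_invalid_input")
  expect_true(all(c("gNa_scale", "g_bacnav") %in% model_parameters("human")))
  expect_true(all(c("gto_max", "gKs", "gKr", "tauh_factor") %in%
                  model_parameters("guineapig")))
})

test_that("paced human myocyte shows adult ventricular AP physiology", {
  cell <- paced_human()
  ap <- simulate_ap(cell, record_dt = 0.05)
  f <- attr(ap, "features")
  expect_gt(f$rmp, -92); expect_lt(f$rmp, -84)
  expect_gt(f$apa, 100); expect_lt(f$apa, 145)
  expect_gt(unname(f$apd["apd90"]), 220); expect_lt(unname(f$apd["apd90"]), 320)
  expect_gt(f$dvdt_max, 150); expect_lt(f$dvdt_max, 400)
})

test_that("the human baseline trace matches the stored regression fixture", {
  cell <- paced_human()
  ap <- simulate_ap(cell, record_dt = 1)
  fix <- read.csv(test_path("fixtures", "human_baseline_vm.csv"))
  got <- ap$vm_mV[match(fix$time_ms, round(ap$time_ms, 6))]
  expect_false(anyNA(got))
  expect_lt(max(abs(got - fix$vm_mV)), 1e-3)
})

test_that("a cell with BacNav at 0X reproduces the base model exactly", {
  base <- build_cell("human")
  zero <- build_cell("human", x_level = 0)
  a <- simulate_ap(base, record_dt = 0.5, rate_hz = 2)
  b <- simulate_ap(zero, record_dt = 0.5, rate_hz = 2)
  expect_identical(a$vm_mV, b$vm_mV)
  expect_true(all(a$I_BacNav == 0))
})

test_that("halving gNa halves the peak clamp sodium current", {
  iv1 <- voltage_clamp(build_cell("human"), steps = c(-30, -20, -10),
                       step_ms = 100, current = "I_Na")
  iv2 <- voltage_clamp(build_cell("human", gNa_scale = 0.5),
                       steps = c(-30, -20, -10), step_ms = 100,
                       current = "I_Na")
  expect_equal(max(abs(iv2$peak)) / max(abs(iv1$peak)), 0.5, tolerance = 0.02)
})

test_that("pacing convergence bookkeeping is honest", {
  cell <- build_cell("guineapig")
  # a vacuous criterion converges after one beat (the relative change per
  # state is bounded by 200% of the larger magnitude)
  pr <- pace_to_equilibrium(cell, 3.33, criterion_pct = 250, max_beats = 5)
  expect_true(pr$converged)
  expect_identical(pr$beats, 1L)
  # once converged at a criterion, an extra beat stays within that criterion
  pr2 <- pace_to_equilibrium(paced_human(), 1, criterion_pct = 2,
                             max_beats = 10)
  expect_true(pr2$converged)
  pr2b <- pace_to_equilibrium(pr2$cell, 1, criterion_pct = 2, max_beats = 3)
  expect_true(pr2b$converged)
  expect_lte(pr2b$beats, 2L)
  expect_lt(pr2b$max_rel_change_pct, 2)
  # guinea pig at its sinus rate captures and settles within a beat budget
  pr3 <- pace_to_equilibrium(build_cell("guineapig"), 3.33,
                             criterion_pct = 0.2, max_beats = 80)
  expect_true(pr3$converged)
  expect_error(pace_to_equilibrium(cell, -1), class = "bacnavsim_invalid_input")
})

test_that("halving the time step changes APD80 and peak Vm by < 0.5%", {
  cell <- paced_human()
  cell$dt <- 0.005
  fine <- cell
  fine$dt <- 0.0025
  a <- simulate_ap(cell, record_dt = 0.05)
  b <- simulate_ap(fine, record_dt = 0.05)
  fa <- attr(a, "features"); fb <- attr(b, "features")
  expect_lt(abs(fa$apd["apd80"] - fb$apd["apd80"]) / fb$apd["apd80"], 0.005)
  expect_lt(abs(fa$peak_vm - fb$peak_vm) / abs(fb$peak_vm), 0.005)
})

test_that("every registered current enters dVm/dt exactly once", {
  # without stimulus or coupling the forward-Euler update gives
  # (V[n+1] - V[n])/dt = -I_total[n] identically; the recorded components
  # must also sum to the recorded total
  cell <- paced_human()
  st <- bacnavsim:::cell_state_matrix(cell)
  pm <- bacnavsim:::cell_param_matrix(cell)
  r <- bacnavsim:::run_nodes("human", pm, st, 0.01, 2, record_dt = 0.01,
                             record_nodes = 1L, record_currents = TRUE)
  cur <- matrix(r$currents, nrow = dim(r$currents)[1])[seq_len(r$n_rec), ]
  colnames(cur) <- c("I_Na", "I_NaL", "I_to", "I_CaL", "I_Kr", "I_Ks",
                     "I_K1", "I_NaCa", "I_NaK", "I_other", "I_BacNav",
                     "I_total")
  comp_sum <- rowSums(cur[, 1:11])
  expect_equal(comp_sum, cur[, "I_total"], tolerance = 1e-12)
  # the forward difference of the stored Vm loses ~eps*|Vm|/dt of absolute
  # precision; 1e-6 still catches any unaccounted current by many orders
  dv <- diff(r$vm[, 1]) / 0.01
  expect_equal(dv, -cur[-nrow(cur), "I_total"], tolerance = 1e-6)
})

test_that("numerical blow-up raises an integration-failure condition with location", {
  cell <- build_cell("human")
  cond <- tryCatch({
    st <- bacnavsim:::cell_state_matrix(cell)
    pm <- bacnavsim:::cell_param_matrix(cell)
    bacnavsim:::run_nodes("human", pm, st, 0.01, 50, stim_nodes = 1L,
                          stim_amp = -1e5, stim_dur = 50, stim_starts = 0)
    NULL
  }, bacnavsim_integration_failure = function(e) e)
  expect_s3_class(cond, "bacnavsim_integration_failure")
  expect_match(conditionMessage(cond), "node 1")
})

test_that("voltage clamp measures near-zero current at the holding potential", {
  cell <- build_cell("human", x_level = 1, gbar_1x = 1)
  iv <- voltage_clamp(cell, holding = -80, steps = -80, step_ms = 100,
                      current = "I_BacNav")
  expect_lt(abs(iv$peak), 0.05)
})
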