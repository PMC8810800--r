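# AP feature extraction on closed-form traces

square_ap <- function(dt = 0.1) {
  t <- seq(0, 400, by = dt)
  v <- ifelse(t >= 50 & t < 250, 20, -80)
  list(t = t, v = v)
}

test_that("rectangular pulse gives APA = 100 and APD at the pulse width", {
  tr <- square_ap()
  f <- ap_features(tr$t, tr$v, stim_ms = 50)
  expect_equal(f$rmp, -80)
  expect_equal(f$apa, 100)
  expect_equal(unname(f$apd["apd80"]), 200, tolerance = 0.01)
  expect_equal(unname(f$apd["apd90"]), 200, tolerance = 0.01)
})

test_that("triangular repolarization follows similar triangles", {
  dt <- 0.1
  t <- seq(0, 400, by = dt)
  v <- rep(-80, length(t))
  up <- t >= 50 & t < 51          # 1 ms upstroke to +20
  v[up] <- -80 + (t[up] - 50) * 100
  dn <- t >= 51 & t <= 351        # linear fall +20 -> -80 over 300 ms
  v[dn] <- 20 - (t[dn] - 51) / 3
  f <- ap_features(t, v, stim_ms = 50)
  expect_equal(f$apa, 100, tolerance = 1e-6)
  # APD_p = p% of the 300 ms fall, measured from the max-dV/dt instant
  for (p in c(20, 50, 80, 90)) {
    expect_equal(unname(f$apd[paste0("apd", p)]), 3 * p + (51 - f$t_dvdt_max),
                 tolerance = 0.5)
  }
  expect_true(f$apd["apd20"] <= f$apd["apd50"] &&
              f$apd["apd50"] <= f$apd["apd80"] &&
              f$apd["apd80"] <= f$apd["apd90"])
})

test_that("crossing times are exact for piecewise-linear traces at any sampling phase", {
  for (phase in c(0, 0.03, 0.07)) {
    t <- seq(0, 400, by = 0.1) + phase
    v <- rep(-80, length(t))
    v[t >= 50 & t < 51] <- -80 + (t[t >= 50 & t < 51] - 50) * 100
    dn <- t >= 51 & t <= 351
    v[dn] <- 20 - (t[dn] - 51) / 3
    v[t > 351] <- -80
    f <- ap_features(t, v, stim_ms = 50)
    # linear interpolation recovers the analytic crossing regardless of phase
    expect_equal(unname(f$apd["apd80"]) + f$t_dvdt_max - 51, 240,
                 tolerance = 0.2)
  }
})

test_that("features shift correctly under time and voltage offsets", {
  tr <- square_ap()
  f0 <- ap_features(tr$t, tr$v, 50)
  f_t <- ap_features(tr$t + 1000, tr$v, 1050)
  expect_equal(unname(f_t$apd), unname(f0$apd))
  expect_equal(f_t$apa, f0$apa)
  f_v <- ap_features(tr$t, tr$v + 15, 50)
  expect_equal(f_v$rmp, f0$rmp + 15)
  expect_equal(f_v$apa, f0$apa)
  expect_equal(unname(f_v$apd), unname(f0$apd))
})

test_that("subthreshold traces raise a no-AP condition", {
  t <- seq(0, 100, by = 0.1)
  v <- -80 + 5 * exp(-(t - 50)^2 / 20) * (t > 50)
  expect_error(ap_features(t, v, 50), class = "bacnavsim_no_ap")
})
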