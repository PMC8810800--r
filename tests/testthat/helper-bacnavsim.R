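# shared helpers for the test suite; heavyweight equilibria are memoized in
# the package's session cache, so repeated calls across files are cheap

paced_human <- function() {
  pd <- bacnavsim:::prepaced_dose_cell("human", criterion_pct = 0.01,
                                       max_beats = 50)
  pd$cell
}

paced_guineapig <- function() {
  pd <- bacnavsim:::prepaced_dose_cell("guineapig", criterion_pct = 0.01,
                                       max_beats = 50)
  pd$cell
}

# session-memoized calibrated 1X conductances
gbar_human <- function() default_gbar_1x("human")
gbar_gp <- function() default_gbar_1x("guineapig")

# toy cable conduction velocity for a given diffusion coefficient (cm^2/ms):
# 100-node cable, direct engine call, activation from max-dVm/dt times
toy_cable_cv <- function(D, dx = 0.01, dt = 0.005, length_cm = 1.5) {
  n <- round(length_cm / dx)
  cell <- make_toy_model(dt = dt)
  state <- matrix(rep(cell$state, n), ncol = n)
  pm <- matrix(cell$params, ncol = 1)
  nbrs <- bacnavsim:::cable_neighbors(n)
  r <- bacnavsim:::run_nodes("toy", pm, state, dt, 300,
                             stim_nodes = 1:5, stim_amp = 120, stim_dur = 2,
                             stim_starts = 1, coupling = D / dx^2,
                             nbrs = nbrs, act_threshold = -20,
                             stop_on_full_activation = TRUE, stop_margin = 5)
  act <- ifelse(is.na(r$thresh_time), NA_real_, r$act_time)
  pos <- (seq_len(n) - 0.5) * dx
  # fit away from the source (slow fronts develop over ~0.5 cm) and the
  # far no-flux boundary
  measure_cv(act, pos, fit_window = which(pos >= 0.8 & pos <= 1.4))
}

# O'Hara-Rudy mini-cable CV at a given discretization, seeded from the
# cached single-cell equilibrium (planar 1D analogue of the tissue runs)
ord_minicable_cv <- function(dx = 0.01, dt = 0.01, length_cm = 0.5) {
  cell <- paced_human()
  n <- round(length_cm / dx)
  state <- matrix(rep(cell$state, n), ncol = n)
  pm <- matrix(cell$params, ncol = 1)
  nbrs <- bacnavsim:::cable_neighbors(n)
  D <- bacnavsim:::diffusion_coefficient(10, 0.4)
  r <- bacnavsim:::run_nodes("human", pm, state, dt, 60,
                             stim_nodes = seq_len(max(3, round(0.03 / dx))),
                             stim_amp = 150, stim_dur = 1, stim_starts = 1,
                             coupling = D / dx^2, nbrs = nbrs,
                             stop_on_full_activation = TRUE, stop_margin = 5)
  act <- ifelse(is.na(r$thresh_time), NA_real_, r$act_time)
  measure_cv(act, (seq_len(n) - 0.5) * dx)
}
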