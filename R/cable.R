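#' Configure a 1D monodomain cable
#'
#' Geometry follows the propagation experiments: 100 cells of 100 um length
#' and 10 um radius (1 cm total), intracellular resistivity 0.4 kOhm.cm,
#' one node per cell. The effective diffusion coefficient of the monodomain
#' reduction is D = a / (2 Ri Cm) with Cm = 1 uF/cm^2.
#'
#' @param species,x_level,gbar_1x,gNa_scale,conductances Passed to
#'   [build_cell()].
#' @param n_cells Number of cells (>= 10).
#' @param cell_length_um,radius_um,ri_kohm_cm,cm_uf_cm2 Cable geometry.
#' @param dt Integrator step (ms).
#' @param stim_cells Indices of stimulated cells (default first 3).
#' @param stim_dur Stimulus duration (ms).
#' @param stim_amp Amplitude (uA/uF); `NULL` = 2x single-cell threshold.
#' @param rate_hz Pacing rate (`NULL` = species sinus rate).
#' @param n_conditioning_beats Propagated beats run before the measured beat.
#' @param prepace_beats,prepace_criterion_pct Single-cell pre-pacing budget
#'   used to seed the cable state.
#' @param window_ms Activation window for the measured beat.
#' @return A `cable_config` list.
#' @export
cable_config <- function(species = "human", x_level = 0, gbar_1x = NULL,
                         gNa_scale = 1, conductances = list(),
                         n_cells = 100, cell_length_um = 100,
                         radius_um = 10, ri_kohm_cm = 0.4, cm_uf_cm2 = 1,
                         dt = 0.01, stim_cells = 1:3, stim_dur = 1,
                         stim_amp = NULL, rate_hz = NULL,
                         n_conditioning_beats = 2,
                         prepace_beats = 50, prepace_criterion_pct = 0.01,
                         window_ms = 150) {
  if (n_cells < 10) stop_bacnavsim("bacnavsim_invalid_input", "`n_cells` must be >= 10")
  for (v in c(cell_length_um, radius_um, ri_kohm_cm, cm_uf_cm2)) {
    if (!is.finite(v) || v <= 0) {
      stop_bacnavsim("bacnavsim_invalid_input", "geometry values must be > 0")
    }
  }
  structure(list(species = species, x_level = x_level, gbar_1x = gbar_1x,
                 gNa_scale = gNa_scale, conductances = conductances,
                 n_cells = n_cells, cell_length_um = cell_length_um,
                 radius_um = radius_um, ri_kohm_cm = ri_kohm_cm,
                 cm_uf_cm2 = cm_uf_cm2, dt = dt, stim_cells = stim_cells,
                 stim_dur = stim_dur, stim_amp = stim_amp, rate_hz = rate_hz,
                 n_conditioning_beats = n_conditioning_beats,
                 prepace_beats = prepace_beats,
                 prepace_criterion_pct = prepace_criterion_pct,
                 window_ms = window_ms),
            class = "cable_config")
}

# monodomain diffusion coefficient, cm^2/ms
diffusion_coefficient <- function(radius_um, ri_kohm_cm, cm_uf_cm2 = 1) {
  a_cm <- radius_um * 1e-4
  ri_ohm_cm <- ri_kohm_cm * 1000
  # 2 * Ri * Cm has units (ohm cm)(uF/cm^2) = us/cm -> convert to ms/cm
  a_cm / (2 * ri_ohm_cm * cm_uf_cm2 * 1e-3)
}

cable_neighbors <- function(n) {
  cbind(c(-1L, seq_len(n - 1) - 1L), c(seq.int(2L, n) - 1L, -1L))
}

# Diastolic threshold of a coupled (cable/tissue) configuration: bisection
# on the amplitude of the rectangular pulse needed to launch a propagating
# wave (a majority of nodes activate within the probe window). The
# electrotonic load of the resting neighbors makes this threshold higher
# than the single-cell one, so it is measured in situ and cached.
coupled_threshold <- function(species, pm, state, dt, coupling, nbrs,
                              stim_nodes, stim_dur, lower = 0, upper = 400,
                              tol = 2, probe_ms = 40,
                              criterion = c("wave", "local")) {
  criterion <- match.arg(criterion)
  key <- paste0("cthr:", species, ":", paste(signif(pm[, 1], 8), collapse = ","),
                ":", ncol(state), ":", length(stim_nodes), ":", stim_dur, ":",
                signif(coupling, 8), ":", criterion)
  hit <- .bacnavsim_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- ncol(state)
  captures <- function(amp) {
    r <- run_nodes(species, pm, state, dt, probe_ms, stim_nodes = stim_nodes,
                   stim_amp = amp, stim_dur = stim_dur, stim_starts = 1,
                   coupling = coupling, nbrs = nbrs,
                   stop_on_full_activation = TRUE, stop_margin = 0)
    if (criterion == "wave") r$n_activated > n / 2
    else !any(is.na(r$thresh_time[stim_nodes]))
  }
  if (!captures(upper)) {
    stop_bacnavsim("bacnavsim_no_capture",
                   "upper bracket amplitude fails to capture")
  }
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  .bacnavsim_cache[[key]] <- hi
  hi
}

# 2x the in-situ diastolic threshold; for configurations where no amplitude
# launches a propagating wave (true conduction block), fall back to local
# capture of the stimulated nodes so block runs have a well-defined stimulus
coupled_stim_amp <- function(species, pm, state, dt, coupling, nbrs,
                             stim_nodes, stim_dur) {
  thr <- tryCatch(
    coupled_threshold(species, pm, state, dt, coupling, nbrs, stim_nodes,
                      stim_dur, criterion = "wave"),
    bacnavsim_no_capture = function(e) {
      coupled_threshold(species, pm, state, dt, coupling, nbrs, stim_nodes,
                        stim_dur, criterion = "local")
    })
  2 * thr
}

#' Run a 1D cable propagation experiment
#'
#' Tiles the single-cell equilibrated state along the cable, runs
#' conditioning propagated beats, then measures activation times (instant of
#' maximum dVm/dt per node, gated on a -20 mV threshold crossing),
#' conduction velocity, and conduction block on the final beat.
#'
#' @param config A [cable_config()].
#' @param record_vm Record Vm(t, x) for the measured beat (at `record_dt`)?
#' @param record_dt Trace resolution (ms).
#' @return A list of class `cable_result`: `act_time_ms` (NA where not
#'   activated), `max_dvdt`, `cv_cm_s` (NA under block), `blocked`,
#'   `last_activated`, `positions_cm`, plus `times`/`vm` when recorded.
#' @export
run_cable <- function(config, record_vm = FALSE, record_dt = 0.5) {
  stopifnot(inherits(config, "cable_config"))
  pd <- prepaced_dose_cell(config$species, x_level = config$x_level,
                           gbar_1x = config$gbar_1x,
                           gNa_scale = config$gNa_scale,
                           conductances = config$conductances,
                           dt = config$dt, stim_dur = config$stim_dur,
                           rate_hz = config$rate_hz,
                           criterion_pct = config$prepace_criterion_pct,
                           max_beats = config$prepace_beats)
  cell <- pd$cell
  pr <- pd$prepace
  rate <- config$rate_hz %||% cell$pacing_hz
  cl <- 1000 / rate
  n <- config$n_cells
  state <- matrix(rep(cell$state, n), ncol = n,
                  dimnames = list(names(cell$state), NULL))
  pm <- cell_param_matrix(cell)
  dx <- config$cell_length_um * 1e-4  # cm
  D <- diffusion_coefficient(config$radius_um, config$ri_kohm_cm,
                             config$cm_uf_cm2)
  coupling <- D / dx^2
  nbrs <- cable_neighbors(n)
  amp <- config$stim_amp %||%
    coupled_stim_amp(config$species, pm, state, config$dt, coupling, nbrs,
                     config$stim_cells, config$stim_dur)

  for (b in seq_len(config$n_conditioning_beats)) {
    res <- run_nodes(config$species, pm, state, config$dt, cl,
                     stim_nodes = config$stim_cells, stim_amp = amp,
                     stim_dur = config$stim_dur, stim_starts = 0,
                     coupling = coupling, nbrs = nbrs)
    state <- res$state
  }
  res <- run_nodes(config$species, pm, state, config$dt, config$window_ms,
                   stim_nodes = config$stim_cells, stim_amp = amp,
                   stim_dur = config$stim_dur, stim_starts = 1,
                   coupling = coupling, nbrs = nbrs,
                   record_dt = if (record_vm) record_dt else -1,
                   record_nodes = if (record_vm) seq_len(n) else integer(),
                   stop_on_full_activation = !record_vm, stop_margin = 10,
                   stall_ms = if (record_vm) -1 else 25)
  act <- ifelse(is.na(res$thresh_time), NA_real_, res$act_time)
  positions <- (seq_len(n) - 0.5) * dx
  blocked <- any(is.na(act[-config$stim_cells]))
  cv <- if (blocked) NA_real_ else {
    tryCatch(measure_cv(act, positions), bacnavsim_error = function(e) NA_real_)
  }
  out <- list(config = config, act_time_ms = act,
              thresh_time_ms = res$thresh_time, max_dvdt = res$max_dvdt,
              cv_cm_s = cv, blocked = blocked,
              last_activated = if (any(!is.na(act))) max(which(!is.na(act))) else 0L,
              positions_cm = positions, stim_amp = amp, prepace = pr)
  if (record_vm) {
    out$times <- res$times
    out$vm <- res$vm
  }
  class(out) <- "cable_result"
  out
}

#' @export
print.cable_result <- function(x, ...) {
  cat(sprintf("<cable_result> %s, %d cells: %s\n", x$config$species,
              x$config$n_cells,
              if (x$blocked) sprintf("conduction block (last activated cell %d)", x$last_activated)
              else sprintf("CV = %.1f cm/s", x$cv_cm_s)))
  invisible(x)
}

#' Conduction velocity from activation times
#'
#' Least-squares slope of position against activation time over a central
#' fit window (default cells 30-70), in cm/s.
#'
#' @param activation_ms Per-node activation times (ms); NA = not activated.
#' @param positions_cm Node positions (cm).
#' @param fit_window Indices used for the fit.
#' @return CV in cm/s.
#' @export
measure_cv <- function(activation_ms, positions_cm,
                       fit_window = NULL) {
  n <- length(activation_ms)
  if (length(positions_cm) != n) {
    stop_bacnavsim("bacnavsim_invalid_input", "positions and times differ in length")
  }
  fit_window <- fit_window %||%
    seq.int(max(1L, round(0.3 * n)), min(n, round(0.7 * n)))
  t <- activation_ms[fit_window]
  x <- positions_cm[fit_window]
  if (any(is.na(t))) {
    stop_bacnavsim("bacnavsim_block",
                   "unactivated node inside the fit window; CV undefined")
  }
  if (length(t) < 5L) {
    stop_bacnavsim("bacnavsim_invalid_input", "need >= 5 activated positions")
  }
  if (max(t) - min(t) < 1e-9) {
    stop_bacnavsim("bacnavsim_estimator_degenerate",
                   "all activation times equal; slope undefined")
  }
  slope <- unname(coef(lm(x ~ t))[2])  # cm/ms
  slope * 1000
}

#' Detect conduction block in a cable result
#'
#' Block is declared when any cell beyond the stimulated region fails to
#' cross the activation threshold within the observation window.
#'
#' @param result A `cable_result`.
#' @param window_ms Observation window (defaults to the run's window).
#' @return List with `block` (logical) and `last_activated` (cell index).
#' @export
detect_block <- function(result, window_ms = NULL) {
  stopifnot(inherits(result, "cable_result"))
  tt <- result$thresh_time_ms
  if (!is.null(window_ms)) tt[tt > window_ms] <- NA
  nonstim <- setdiff(seq_along(tt), result$config$stim_cells)
  act <- which(!is.na(tt))
  list(block = any(is.na(tt[nonstim])),
       last_activated = if (length(act)) max(act) else 0L)
}
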