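#' Build a host ventricular myocyte model with optional BacNav
#'
#' Constructs a cell model: the O'Hara-Rudy human adult ventricular myocyte
#' (endocardial parameterization), a guinea-pig ventricular myocyte of the
#' Luo-Rudy lineage (with IKr/IKs split and a transient outward current for
#' transmural work), or a fast two-variable toy excitable cell used to
#' verify the solvers. BacNav is attached as an additive current
#' `x_level * gbar_1x * m * h * (Vm - E_Na)`.
#'
#' @param species `"human"`, `"guineapig"` or `"toy"`.
#' @param x_level BacNav expression multiplier (0 = absent).
#' @param gbar_1x BacNav maximal conductance at 1X (mS/uF). `NULL` with
#'   `x_level > 0` uses a session-cached value from [calibrate_1x()].
#' @param e_rev BacNav reversal potential (mV); `NA` = host sodium Nernst
#'   potential.
#' @param gNa_scale Multiplier on the endogenous sodium conductance
#'   (both fast and late components for the human model).
#' @param conductances Named list of additional engine parameters to set
#'   (e.g. `list(gKs_scale = 2)` for human, `list(gto_max = 0.25)` for
#'   guinea pig); names must match [model_parameters()] for the species.
#' @param pacing_hz Default pacing rate; sinus rates by species (1 Hz human,
#'   3.33 Hz guinea pig) when `NULL`.
#' @param dt Integrator step (ms). Hodgkin-Huxley gates use exact
#'   (Rush-Larsen) relaxation; Vm and concentrations use forward Euler.
#' @param stim_amp Stimulus amplitude (uA/uF); `NULL` = twice the diastolic
#'   threshold, found by bisection once per configuration.
#' @param stim_dur Stimulus duration (ms).
#' @return An object of class `bacnav_cell`.
#' @export
build_cell <- function(species = c("human", "guineapig", "toy"),
                       x_level = 0, gbar_1x = NULL, e_rev = NA_real_,
                       gNa_scale = 1, conductances = list(),
                       pacing_hz = NULL, dt = 0.01,
                       stim_amp = NULL, stim_dur = 1) {
  species <- tryCatch(match.arg(species), error = function(e) {
    stop_bacnavsim("bacnavsim_unsupported_model",
                   sprintf("unknown species '%s'", species[1]))
  })
  info <- .model_info(species)
  params <- info$default_params
  state <- info$default_state
  check_finite_scalar(x_level, "x_level")
  if (x_level < 0) stop_bacnavsim("bacnavsim_invalid_input", "`x_level` must be >= 0")
  check_finite_scalar(gNa_scale, "gNa_scale")

  if (species %in% c("human", "guineapig")) {
    params[["gNa_scale"]] <- gNa_scale
    if (species == "human") params[["gNaL_scale"]] <- gNa_scale
    if (x_level > 0) {
      if (is.null(gbar_1x)) gbar_1x <- default_gbar_1x(species)
      params[["g_bacnav"]] <- x_level * gbar_1x
    }
    params[["e_bacnav"]] <- e_rev
  }
  for (nm in names(conductances)) {
    if (!nm %in% names(params)) {
      stop_bacnavsim("bacnavsim_invalid_input",
                     sprintf("unknown parameter '%s' for species '%s'", nm, species))
    }
    params[[nm]] <- conductances[[nm]]
  }
  if (is.null(pacing_hz)) {
    pacing_hz <- switch(species, human = 1, guineapig = 3.33, toy = 1)
  }
  structure(list(species = species, params = params, state = state,
                 dt = dt, pacing_hz = pacing_hz,
                 stim_amp = stim_amp, stim_dur = stim_dur,
                 x_level = x_level, gbar_1x = gbar_1x %||% NA_real_),
            class = "bacnav_cell")
}

#' @export
print.bacnav_cell <- function(x, ...) {
  cat(sprintf("<bacnav_cell> species=%s  x_level=%g  gNa_scale=%g  Vm=%.2f mV\n",
              x$species, x$x_level,
              x$params[["gNa_scale"]] %||% 1, x$state[["vm"]]))
  invisible(x)
}

#' Names of the tunable parameters of an ionic model
#' @param species Model name as in [build_cell()].
#' @return Character vector of engine parameter names.
#' @export
model_parameters <- function(species) {
  names(.model_info(species)$default_params)
}

# low-level single/multi-node run; state is ns x n, params np x (1|n)
run_nodes <- function(species, params, state, dt, duration, t0 = 0,
                      stim_nodes = integer(), stim_amp = 0, stim_dur = 1,
                      stim_starts = numeric(), coupling = 0,
                      nbrs = matrix(integer(), 0, 0),
                      record_dt = -1, record_nodes = integer(),
                      record_currents = FALSE, act_threshold = -20,
                      measure_from = 0, stop_on_full_activation = FALSE,
                      stop_margin = 5, stall_ms = -1, vmax_abort = 500) {
  res <- .sim_run(species, params, state, dt, duration, t0,
                  as.integer(stim_nodes - 1L), stim_amp, stim_dur,
                  stim_starts, coupling, nbrs,
                  record_dt, as.integer(record_nodes - 1L),
                  record_currents, act_threshold, measure_from,
                  stop_on_full_activation, stop_margin, stall_ms, vmax_abort)
  if (isTRUE(res$aborted)) {
    info <- .model_info(species)
    stop_bacnavsim("bacnavsim_integration_failure",
                   sprintf("numerical blow-up in state 'vm' at node %d, t = %.3f ms",
                           res$abort_node, res$abort_time))
  }
  res
}

cell_state_matrix <- function(cell) {
  matrix(cell$state, ncol = 1, dimnames = list(names(cell$state), NULL))
}

cell_param_matrix <- function(cell) {
  matrix(cell$params, ncol = 1, dimnames = list(names(cell$params), NULL))
}

#' Diastolic stimulus threshold of a single cell
#'
#' Bisects the amplitude of a rectangular current pulse (duration
#' `cell$stim_dur`) that elicits an action potential (peak Vm > 0 mV) from
#' the cell's present state.
#'
#' @param cell A [build_cell()] object.
#' @param lower,upper Bracketing amplitudes (uA/uF).
#' @param tol Bisection tolerance (uA/uF).
#' @return Threshold amplitude (uA/uF).
#' @export
find_threshold <- function(cell, lower = 0, upper = 200, tol = 0.5) {
  key <- paste0("thr:", cell$species, ":",
                paste(signif(cell$params, 8), collapse = ","),
                ":", cell$stim_dur, ":", signif(cell$state[["vm"]], 6))
  hit <- .bacnavsim_cache[[key]]
  if (!is.null(hit)) return(hit)
  fires <- function(amp) {
    res <- run_nodes(cell$species, cell_param_matrix(cell),
                     cell_state_matrix(cell), cell$dt, 60,
                     stim_nodes = 1L, stim_amp = amp,
                     stim_dur = cell$stim_dur, stim_starts = 0,
                     record_dt = 0.5, record_nodes = 1L)
    max(res$vm[, 1]) > 0
  }
  if (!fires(upper)) {
    stop_bacnavsim("bacnavsim_no_capture",
                   "upper bracket amplitude fails to elicit an AP")
  }
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .bacnavsim_cache[[key]] <- hi
  hi
}

cell_stim_amp <- function(cell) {
  if (!is.null(cell$stim_amp)) return(cell$stim_amp)
  2 * find_threshold(cell)
}

# Pre-paced cell for tissue-scale runs: the host is equilibrated with BacNav
# detached, then BacNav is attached with its gates initialized at the
# resting potential. Cached per configuration (the host equilibrium is
# shared by all expression levels).
prepaced_dose_cell <- function(species, x_level = 0, gbar_1x = NULL,
                               gNa_scale = 1, conductances = list(),
                               dt = 0.01, stim_dur = 1, rate_hz = NULL,
                               criterion_pct = 0.01, max_beats = 50) {
  host <- build_cell(species, x_level = 0, gNa_scale = gNa_scale,
                     conductances = conductances, dt = dt,
                     stim_dur = stim_dur)
  rate_hz <- rate_hz %||% host$pacing_hz
  key <- paste0("prepace:", species, ":",
                paste(signif(host$params, 8), collapse = ","), ":",
                dt, ":", rate_hz, ":", criterion_pct, ":", max_beats)
  pr <- .bacnavsim_cache[[key]]
  if (is.null(pr)) {
    pr <- pace_to_equilibrium(host, rate_hz, criterion_pct = criterion_pct,
                              max_beats = max_beats)
    .bacnavsim_cache[[key]] <- pr
  }
  cell <- pr$cell
  if (x_level > 0) {
    if (is.null(gbar_1x)) gbar_1x <- default_gbar_1x(species)
    cell$params[["g_bacnav"]] <- x_level * gbar_1x
    cell$state[["m_bac"]] <- m_inf(cell$state[["vm"]])
    cell$state[["h_bac"]] <- h_inf(cell$state[["vm"]])
    cell$x_level <- x_level
    cell$gbar_1x <- gbar_1x
  }
  list(cell = cell, prepace = pr[c("beats", "converged", "max_rel_change_pct")])
}

#' Pace a cell to equilibrium
#'
#' Applies the cell's stimulus at the given rate; after every beat computes
#' the maximum relative change of any state variable over the beat (in %)
#' and stops when this falls below `criterion_pct` (the convergence
#' criterion is variability below 0.001 %/beat at full scale) or at
#' `max_beats`.
#'
#' @param cell A [build_cell()] object.
#' @param rate_hz Pacing rate; defaults to the cell's sinus rate.
#' @param criterion_pct Per-beat maximum relative state change (%).
#' @param max_beats Beat budget.
#' @return A list of class `pacing_result`: `cell` (with updated state),
#'   `beats`, `converged`, `max_rel_change_pct`, `per_beat`.
#' @export
pace_to_equilibrium <- function(cell, rate_hz = NULL, criterion_pct = 0.001,
                                max_beats = 200) {
  rate_hz <- rate_hz %||% cell$pacing_hz
  if (rate_hz <= 0) stop_bacnavsim("bacnavsim_invalid_input", "`rate_hz` must be > 0")
  if (criterion_pct <= 0) {
    stop_bacnavsim("bacnavsim_invalid_input", "`criterion_pct` must be > 0")
  }
  cl <- 1000 / rate_hz
  amp <- cell_stim_amp(cell)
  state <- cell_state_matrix(cell)
  pm <- cell_param_matrix(cell)
  per_beat <- numeric(0)
  converged <- FALSE
  beats <- 0L
  for (b in seq_len(max_beats)) {
    prev <- state[, 1]
    res <- run_nodes(cell$species, pm, state, cell$dt, cl,
                     stim_nodes = 1L, stim_amp = amp,
                     stim_dur = cell$stim_dur, stim_starts = 0,
                     record_dt = if (b == 1L) 1 else -1,
                     record_nodes = if (b == 1L) 1L else integer())
    if (b == 1L && max(res$vm[, 1]) < -20) {
      stop_bacnavsim("bacnavsim_no_capture",
                     "stimulus failed to elicit an AP during pacing")
    }
    state <- res$state
    # relative to the larger magnitude so states growing from zero report a
    # bounded (100%) change rather than an unbounded ratio
    delta <- max(abs(state[, 1] - prev) /
                   pmax(abs(prev), abs(state[, 1]), 1e-8)) * 100
    per_beat <- c(per_beat, delta)
    beats <- b
    if (delta < criterion_pct) {
      converged <- TRUE
      break
    }
  }
  cell$state <- structure(state[, 1], names = rownames(state))
  cell$stim_amp <- amp
  structure(list(cell = cell, beats = beats, converged = converged,
                 max_rel_change_pct = per_beat[length(per_beat)],
                 per_beat = per_beat, rate_hz = rate_hz),
            class = "pacing_result")
}

#' @export
print.pacing_result <- function(x, ...) {
  cat(sprintf("<pacing_result> %d beats at %.3g Hz, converged=%s (last change %.3g %%/beat)\n",
              x$beats, x$rate_hz, x$converged, x$max_rel_change_pct))
  invisible(x)
}

#' Simulate paced action potentials and record traces
#'
#' Runs `n_beats` paced beats from the cell's present state and records Vm
#' and all registered membrane currents (including I_BacNav and I_Ks) during
#' the final beat.
#'
#' @param cell A [build_cell()] object (typically pre-paced).
#' @param n_beats Number of beats; only the last is recorded.
#' @param record_dt Trace resolution (ms).
#' @param rate_hz Pacing rate; defaults to the cell's rate.
#' @param stim_offset_ms Stimulus onset within the recorded window.
#' @return A data.frame with `time_ms`, `vm_mV` and one column per current
#'   (uA/uF), with attributes `stim_ms` and `features` ([ap_features()]).
#' @export
simulate_ap <- function(cell, n_beats = 1, record_dt = 0.1, rate_hz = NULL,
                        stim_offset_ms = 10) {
  rate_hz <- rate_hz %||% cell$pacing_hz
  cl <- 1000 / rate_hz
  amp <- cell_stim_amp(cell)
  state <- cell_state_matrix(cell)
  pm <- cell_param_matrix(cell)
  if (n_beats > 1) {
    res <- run_nodes(cell$species, pm, state, cell$dt, cl * (n_beats - 1),
                     stim_nodes = 1L, stim_amp = amp,
                     stim_dur = cell$stim_dur,
                     stim_starts = seq(0, by = cl, length.out = n_beats - 1))
    state <- res$state
  }
  res <- run_nodes(cell$species, pm, state, cell$dt, cl,
                   stim_nodes = 1L, stim_amp = amp, stim_dur = cell$stim_dur,
                   stim_starts = stim_offset_ms,
                   record_dt = record_dt, record_nodes = 1L,
                   record_currents = TRUE)
  info <- .model_info(cell$species)
  nrt <- dim(res$currents)[1]
  cur <- matrix(res$currents, nrow = nrt)[seq_len(res$n_rec), , drop = FALSE]
  colnames(cur) <- info$current_names
  out <- data.frame(time_ms = res$times, vm_mV = res$vm[, 1])
  out <- cbind(out, as.data.frame(cur))
  attr(out, "stim_ms") <- stim_offset_ms
  attr(out, "features") <- tryCatch(
    ap_features(out$time_ms, out$vm_mV, stim_offset_ms),
    bacnavsim_no_ap = function(e) NULL)
  attr(out, "final_state") <- structure(res$state[, 1],
                                        names = names(cell$state))
  out
}

#' Voltage-clamp protocol: peak current per test potential
#'
#' Holds the cell at `holding` until the gates settle, then steps to each
#' test potential for `step_ms` and records the extremal (signed-peak)
#' current of the selected channel during the step.
#'
#' @param cell A [build_cell()] object.
#' @param holding Holding potential (mV).
#' @param steps Test potentials (mV).
#' @param step_ms Step duration (ms); the experimental protocol uses 500 ms.
#' @param settle_ms Settling time at the holding potential before each step.
#' @param current Name of the current to measure (see the `current_names`
#'   of [model_parameters()]'s model), e.g. `"I_Na"` or `"I_BacNav"`.
#' @param record_dt Sampling interval for peak detection (ms).
#' @return A data.frame `step_mV`, `peak` (uA/uF, signed extremum),
#'   `t_peak_ms` (relative to step onset).
#' @export
voltage_clamp <- function(cell, holding = -80, steps = seq(-50, 50, 10),
                          step_ms = 500, settle_ms = 500,
                          current = "I_BacNav", record_dt = 0.05) {
  if (length(steps) == 0L) {
    stop_bacnavsim("bacnavsim_invalid_input", "`steps` must be non-empty")
  }
  info <- .model_info(cell$species)
  ci <- match(current, info$current_names)
  if (is.na(ci)) {
    stop_bacnavsim("bacnavsim_invalid_input",
                   sprintf("model '%s' has no current '%s'", cell$species, current))
  }
  out <- lapply(steps, function(vstep) {
    res <- .sim_vclamp(cell$species, cell$params, cell$state,
                       c(0, settle_ms), c(holding, vstep),
                       settle_ms + step_ms, cell$dt, record_dt)
    inwin <- res$times >= settle_ms
    i <- res$currents[inwin, ci]
    t <- res$times[inwin] - settle_ms
    k <- which.max(abs(i))
    data.frame(step_mV = vstep, peak = i[k], t_peak_ms = t[k])
  })
  do.call(rbind, out)
}
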