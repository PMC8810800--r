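#' Transmural layer specification for the Brugada cable
#'
#' The transmural wedge is a cable of 165 guinea-pig ventricular myocytes:
#' endocardial cells 1-60, midmyocardial cells 61-105, epicardial cells
#' 106-165. Layers differ in maximal transient-outward conductance (endo 0,
#' mid 0.2125, epi 0.25 mS/uF) and in the IKs:IKr conductance ratio (endo
#' 11:1, mid 4:1, epi 35:1; gKr held at its base value).
#'
#' @param sizes Named layer sizes (cells).
#' @param ito_max Per-layer maximal Ito conductance (mS/uF).
#' @param iks_ikr_ratio Per-layer IKs:IKr conductance ratio.
#' @return A `transmural_spec` list.
#' @export
transmural_spec <- function(sizes = c(endo = 60, mid = 45, epi = 60),
                            ito_max = c(endo = 0, mid = 0.2125, epi = 0.25),
                            iks_ikr_ratio = c(endo = 11, mid = 4, epi = 35)) {
  if (sum(sizes) != 165) {
    stop_bacnavsim("bacnavsim_invalid_spec",
                   sprintf("layer sizes sum to %d, not 165", sum(sizes)))
  }
  if (any(ito_max < 0) || any(iks_ikr_ratio <= 0)) {
    stop_bacnavsim("bacnavsim_invalid_spec",
                   "ito_max must be >= 0 and IKs:IKr ratios > 0")
  }
  structure(list(sizes = sizes, ito_max = ito_max,
                 iks_ikr_ratio = iks_ikr_ratio),
            class = "transmural_spec")
}

#' Brugada severity parameterization
#'
#' Severity is modeled by accelerating the fast inactivation of the
#' endogenous sodium current (dividing the tau of the h gate) and scaling
#' the maximal Ito conductance: mild = (1.5, 3), severe = (3.5, 7),
#' none = (1, 1).
#'
#' @param severity `"none"`, `"mild"`, `"severe"`, or a `brugada_severity`.
#' @param inactivation_factor,ito_mult Explicit factors (both >= 1) when not
#'   using a preset.
#' @return A `brugada_severity` list.
#' @export
brugada_severity <- function(severity = c("none", "mild", "severe"),
                             inactivation_factor = NULL, ito_mult = NULL) {
  if (inherits(severity, "brugada_severity")) return(severity)
  if (is.null(inactivation_factor)) {
    severity <- match.arg(severity)
    f <- switch(severity, none = c(1, 1), mild = c(1.5, 3), severe = c(3.5, 7))
    inactivation_factor <- f[1]; ito_mult <- f[2]
  }
  if (inactivation_factor < 1 || ito_mult < 1) {
    stop_bacnavsim("bacnavsim_invalid_input", "severity factors must be >= 1")
  }
  structure(list(inactivation_factor = inactivation_factor,
                 ito_mult = ito_mult),
            class = "brugada_severity")
}

#' Build the transmural guinea-pig cable
#'
#' Assembles the per-cell parameter set of the 165-cell heterogeneous cable
#' with endocardial-end stimulation. BacNav can be attached at a given
#' expression level; Brugada severity is applied with [apply_brugada()].
#'
#' @param spec A [transmural_spec()].
#' @param x_level,gbar_1x BacNav expression (see [build_cell()]).
#' @param dt Integrator step (ms).
#' @param rate_hz Pacing rate (guinea-pig sinus rate 3.33 Hz).
#' @return A list of class `transmural_cable` with `params` (engine
#'   parameter matrix, one column per cell), `layer` (per-cell layer
#'   factor), and geometry fields shared with [cable_config()].
#' @export
build_transmural_cable <- function(spec = transmural_spec(), x_level = 0,
                                   gbar_1x = NULL, dt = 0.01,
                                   rate_hz = 3.33) {
  stopifnot(inherits(spec, "transmural_spec"))
  info <- .model_info("guineapig")
  base <- info$default_params
  gkr <- base[["gKr"]]
  layer <- rep(names(spec$sizes), spec$sizes)
  n <- length(layer)
  pm <- matrix(rep(base, n), ncol = n, dimnames = list(names(base), NULL))
  for (ly in names(spec$sizes)) {
    sel <- layer == ly
    pm["gto_max", sel] <- spec$ito_max[[ly]]
    pm["gKs", sel] <- spec$iks_ikr_ratio[[ly]] * gkr
  }
  g_bac <- 0
  if (x_level > 0) {
    if (is.null(gbar_1x)) gbar_1x <- default_gbar_1x("guineapig")
    g_bac <- x_level * gbar_1x
  }
  pm["g_bacnav", ] <- g_bac
  structure(list(spec = spec, params = pm, layer = layer, n_cells = n,
                 x_level = x_level, gbar_1x = gbar_1x %||% NA_real_,
                 severity = brugada_severity("none"), dt = dt,
                 rate_hz = rate_hz, cell_length_um = 100, radius_um = 10,
                 ri_kohm_cm = 0.4, stim_cells = 1:3, stim_dur = 1),
            class = "transmural_cable")
}

#' Apply a Brugada severity to a transmural cable
#'
#' Divides the fast-inactivation time constant of the endogenous sodium
#' current by the inactivation speed factor and multiplies each layer's
#' maximal Ito conductance by the Ito multiplier.
#'
#' @param cable A [build_transmural_cable()] object.
#' @param severity A [brugada_severity()] or preset name.
#' @return The modified cable.
#' @export
apply_brugada <- function(cable, severity) {
  stopifnot(inherits(cable, "transmural_cable"))
  sev <- brugada_severity(severity)
  cable$params["tauh_factor", ] <-
    cable$params["tauh_factor", ] * sev$inactivation_factor
  cable$params["gto_max", ] <- cable$params["gto_max", ] * sev$ito_mult
  cable$severity <- sev
  cable
}

# single-cell equilibrium of one column of a transmural cable, BacNav
# detached during pacing and re-attached with gates at the resting potential
transmural_layer_state <- function(cable, col) {
  p <- cable$params[, col]
  key <- paste0("tmstate:", paste(signif(p, 8), collapse = ","), ":",
                cable$dt, ":", cable$rate_hz)
  hit <- .bacnavsim_cache[[key]]
  if (!is.null(hit)) return(hit)
  cell <- build_cell("guineapig", dt = cable$dt, stim_dur = cable$stim_dur)
  cell$params <- p
  cell$params[["g_bacnav"]] <- 0
  pr <- pace_to_equilibrium(cell, cable$rate_hz, criterion_pct = 0.01,
                            max_beats = 50)
  st <- pr$cell$state
  st[["m_bac"]] <- m_inf(st[["vm"]])
  st[["h_bac"]] <- h_inf(st[["vm"]])
  .bacnavsim_cache[[key]] <- st
  st
}

#' Run a transmural Brugada propagation experiment
#'
#' Pre-paces one representative cell per layer to equilibrium, tiles the
#' layer states along the 165-cell cable, stimulates the endocardial end,
#' and records the propagated beat for every cell, the representative
#' endo/mid/epi action potentials (cells 30, 80, 150), and the pseudo-ECG
#' at a virtual electrode 2 cm from the epicardial end.
#'
#' @param cable A [build_transmural_cable()] (+ [apply_brugada()]) object.
#' @param window_ms Recorded window (ms).
#' @param record_dt Trace resolution (ms).
#' @param electrode_cm Electrode distance beyond the epicardial end (cm).
#' @param sigma_ratio Intra/extracellular conductivity ratio in the
#'   pseudo-ECG scaling (amplitude only).
#' @return A list of class `transmural_result`: `times`, `vm` (time x cell),
#'   `ecg` (`ecg_trace`), `aps` (list of endo/mid/epi data.frames),
#'   `act_time_ms`, `cable`.
#' @export
run_transmural <- function(cable, window_ms = 280, record_dt = 0.5,
                           electrode_cm = 2, sigma_ratio = 1) {
  stopifnot(inherits(cable, "transmural_cable"))
  n <- cable$n_cells
  cols <- c(1L, which(cable$layer == "mid")[1], which(cable$layer == "epi")[1])
  states <- lapply(cols, function(cc) transmural_layer_state(cable, cc))
  st <- matrix(NA_real_, length(states[[1]]), n,
               dimnames = list(names(states[[1]]), NULL))
  st[, cable$layer == "endo"] <- states[[1]]
  st[, cable$layer == "mid"] <- states[[2]]
  st[, cable$layer == "epi"] <- states[[3]]
  dx <- cable$cell_length_um * 1e-4
  D <- diffusion_coefficient(cable$radius_um, cable$ri_kohm_cm)
  nbrs <- cable_neighbors(n)
  amp <- coupled_stim_amp("guineapig", cable$params, st, cable$dt, D / dx^2,
                          nbrs, cable$stim_cells, cable$stim_dur)
  res <- run_nodes("guineapig", cable$params, st, cable$dt, window_ms,
                   stim_nodes = cable$stim_cells, stim_amp = amp,
                   stim_dur = cable$stim_dur, stim_starts = 5,
                   coupling = D / dx^2, nbrs = nbrs,
                   record_dt = record_dt, record_nodes = seq_len(n))
  positions <- (seq_len(n) - 0.5) * dx
  ecg <- pseudo_ecg(res$vm, res$times, positions,
                    electrode_x_cm = n * dx + electrode_cm,
                    a_um = cable$radius_um, sigma_ratio = sigma_ratio)
  reps <- c(endo = 30, mid = 80, epi = 150)
  aps <- lapply(reps, function(i) {
    data.frame(time_ms = res$times, vm_mV = res$vm[, i])
  })
  act <- ifelse(is.na(res$thresh_time), NA_real_, res$act_time)
  structure(list(times = res$times, vm = res$vm, ecg = ecg, aps = aps,
                 act_time_ms = act, stim_amp = amp, cable = cable),
            class = "transmural_result")
}

#' Pseudo-ECG of a fiber (Plonsey-Barr lead-field integral)
#'
#' Computes the extracellular potential at a point electrode on the fiber
#' axis: phi_e(t) = (a^2 sigma_i / 4 sigma_e) * sum_x (-dVm/dx) d(1/r)/dx dx,
#' with central differences in space and the Euclidean source-electrode
#' distance r. phi_e is zero whenever Vm is spatially uniform, and linear in
#' Vm; the conductivity ratio only scales the amplitude.
#'
#' @param vm Matrix of Vm samples, time in rows, position in columns (mV).
#' @param times Sample times (ms).
#' @param x_cm Node positions along the fiber (cm).
#' @param electrode_x_cm Electrode position along the axis (cm); must not
#'   coincide with a source node.
#' @param a_um Fiber radius (um).
#' @param sigma_ratio sigma_i / sigma_e.
#' @return A list of class `ecg_trace`: `times`, `phi` (mV-scaled arbitrary
#'   units), `electrode_x_cm`.
#' @export
pseudo_ecg <- function(vm, times, x_cm, electrode_x_cm, a_um = 10,
                       sigma_ratio = 1) {
  vm <- as.matrix(vm)
  nx <- ncol(vm)
  if (length(x_cm) != nx || nrow(vm) != length(times)) {
    stop_bacnavsim("bacnavsim_invalid_input", "vm, times, x_cm dimensions disagree")
  }
  r <- abs(electrode_x_cm - x_cm)
  if (min(r) < 1e-9) {
    stop_bacnavsim("bacnavsim_singular_geometry",
                   "electrode coincides with a source node")
  }
  dx <- diff(x_cm)
  if (any(dx <= 0) || max(dx) - min(dx) > 1e-9 * max(dx)) {
    stop_bacnavsim("bacnavsim_invalid_input", "x_cm must be a uniform grid")
  }
  h <- dx[1]
  ii <- 2:(nx - 1)
  invr <- 1 / r
  dinvr <- (invr[ii + 1] - invr[ii - 1]) / (2 * h)
  k <- (a_um * 1e-4)^2 * sigma_ratio / 4
  # (-dVm/dx) . d(1/r)/dx summed over interior nodes, all time samples at once
  dvm <- (vm[, ii + 1, drop = FALSE] - vm[, ii - 1, drop = FALSE]) / (2 * h)
  phi <- k * as.vector((-dvm) %*% dinvr) * h
  structure(list(times = times, phi = phi, electrode_x_cm = electrode_x_cm,
                 a_um = a_um, sigma_ratio = sigma_ratio),
            class = "ecg_trace")
}

#' ECG deviation score (L1 distance between traces)
#'
#' Resamples both traces onto a common 1 kHz time base and returns the sum
#' of absolute voltage differences over all time points.
#'
#' @param ecg,healthy `ecg_trace` objects (or lists with `times`, `phi`).
#' @param sample_khz Resampling rate (kHz).
#' @return The deviation score (same units as `phi`).
#' @export
ecg_deviation <- function(ecg, healthy, sample_khz = 1) {
  t0 <- max(min(ecg$times), min(healthy$times))
  t1 <- min(max(ecg$times), max(healthy$times))
  if (t1 <= t0) {
    stop_bacnavsim("bacnavsim_alignment", "ECG time bases do not overlap")
  }
  tt <- seq(t0, t1, by = 1 / sample_khz)
  a <- approx(ecg$times, ecg$phi, tt)$y
  b <- approx(healthy$times, healthy$phi, tt)$y
  sum(abs(a - b))
}

#' Detect the phase-2 dome of an action potential
#'
#' Deterministic rule with two branches. (a) Notch-and-dome: a phase-1
#' local minimum within 60 ms of the upstroke peak is followed by a
#' secondary maximum at least 5 mV above the minimum and above the
#' `dome_level`. (b) Sustained plateau: Vm stays continuously above the
#' `dome_level` for at least `plateau_ms` starting within 60 ms of the
#' peak (a plateau without a notch is a dome). The default level of -20 mV
#' sits between this host model's dome apex (around 0 mV) and the
#' collapsed/repolarized range.
#'
#' @param time_ms,vm AP trace.
#' @param dome_level Potential the dome must exceed (mV).
#' @param plateau_ms Minimum duration of a notchless plateau (ms).
#' @return `TRUE` if a dome is present.
#' @export
has_dome <- function(time_ms, vm, dome_level = -20, plateau_ms = 25) {
  ipk <- which.max(vm)
  if (ipk >= length(vm) - 2) return(FALSE)
  tt <- time_ms[ipk:length(vm)] - time_ms[ipk]
  after <- vm[ipk:length(vm)]
  # (a) phase-1 minimum within 60 ms of the peak, then a genuine re-ascent
  dmin <- which(diff(after) >= 0)
  dmin <- dmin[tt[dmin] <= 60]
  if (length(dmin) > 0) {
    imin <- dmin[1]
    vmax2 <- max(after[imin:length(after)])
    if (vmax2 > dome_level && vmax2 - after[imin] >= 5) return(TRUE)
  }
  # (b) sustained notchless plateau above the dome level
  high <- after > dome_level
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    if (tt[starts[k]] <= 60 &&
        tt[ends[k]] - tt[starts[k]] >= plateau_ms) return(TRUE)
  }
  FALSE
}
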