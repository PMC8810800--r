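#' BacNav (h2SheP) gating kinetics
#'
#' Voltage-dependent time constants and steady-state curves of the engineered
#' prokaryotic sodium channel NavSheP D60A (codon-optimized variant h2SheP),
#' modeled with a single activation gate `m` and a single inactivation gate
#' `h`. The fitted forms use a two-exponential denominator that produces
#' asymmetric bell-shaped time constants; the additive offsets (1.66 ms for
#' `m`, 9.593 ms for `h`) are the depolarized asymptotes. Exponential
#' arguments are clamped to +-700 so the steep slope factors (0.2351 and
#' 0.1281 mV) never overflow at physiological potentials.
#'
#' @param vm Membrane potential in mV (finite, vectorized).
#' @return Time constant in ms (`tau_m`, `tau_h`) or dimensionless
#'   steady-state open fraction in (0, 1) (`m_inf`, `h_inf`).
#' @examples
#' tau_m(c(-80, -10, 40))
#' m_inf(-22.5) # half-activation
#' @export
tau_m <- function(vm) {
  check_finite(vm, "vm")
  34.65 / (gexp((vm + 43.47) / 14.36) + gexp(-(vm + 15.75) / 0.2351)) + 1.66
}

#' @rdname tau_m
#' @export
tau_h <- function(vm) {
  check_finite(vm, "vm")
  107.8 / (gexp((vm + 27.15) / 0.1281) + gexp(-(vm + 25.63) / 25.19)) + 9.593
}

#' @rdname tau_m
#' @export
m_inf <- function(vm) {
  check_finite(vm, "vm")
  1 / (1 + gexp((-22.5 - vm) / 2.704))
}

#' @rdname tau_m
#' @export
h_inf <- function(vm) {
  check_finite(vm, "vm")
  1 / (1 + gexp((vm + 77.05) / 10.64))
}

#' Initialize BacNav gates at a holding potential
#'
#' @param v0 Holding potential (mV).
#' @return Named numeric vector `c(m = , h = )` at steady state for `v0`.
#' @export
init_gates <- function(v0 = -80) {
  check_finite_scalar(v0, "v0")
  c(m = m_inf(v0), h = h_inf(v0))
}

#' Advance BacNav gates by exact exponential relaxation
#'
#' One Rush-Larsen step of the first-order gate equations
#' dg/dt = (g_inf(Vm) - g) / tau(Vm) at fixed membrane potential:
#' g' = g_inf + (g - g_inf) exp(-dt / tau). The update is unconditionally
#' bounded in \[0, 1\] for any step size.
#'
#' @param gates Named numeric vector with components `m` and `h` in \[0, 1\].
#' @param vm Membrane potential (mV).
#' @param dt Time step (ms), non-negative.
#' @return Updated gate vector.
#' @export
step_gates <- function(gates, vm, dt) {
  check_finite_scalar(vm, "vm")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0) {
    stop_bacnavsim("bacnavsim_invalid_input", "`dt` must be a finite number >= 0")
  }
  m0 <- unname(gates[["m"]])
  h0 <- unname(gates[["h"]])
  if (dt == 0) return(c(m = m0, h = h0))
  mi <- m_inf(vm)
  hi <- h_inf(vm)
  c(m = mi + (m0 - mi) * exp(-dt / tau_m(vm)),
    h = hi + (h0 - hi) * exp(-dt / tau_h(vm)))
}

#' BacNav channel parameters
#'
#' @param x_level Expression multiplier (dimensionless, >= 0); `1` is the
#'   level calibrated to match the endogenous peak Nav1.5 current (see
#'   [calibrate_1x()]).
#' @param gbar_1x Maximal conductance at 1X expression (mS/uF), > 0.
#' @param e_rev Reversal potential (mV). `NA` means "use the sodium Nernst
#'   potential of the host cell model" (the channel is Na-selective).
#' @return An object of class `bacnav_params`.
#' @export
bacnav_params <- function(x_level = 1, gbar_1x = 1, e_rev = NA_real_) {
  check_finite_scalar(x_level, "x_level")
  check_finite_scalar(gbar_1x, "gbar_1x")
  if (x_level < 0) stop_bacnavsim("bacnavsim_invalid_input", "`x_level` must be >= 0")
  if (gbar_1x <= 0) stop_bacnavsim("bacnavsim_invalid_input", "`gbar_1x` must be > 0")
  if (!is.na(e_rev)) check_finite_scalar(e_rev, "e_rev")
  structure(list(x_level = x_level, gbar_1x = gbar_1x, e_rev = e_rev),
            class = "bacnav_params")
}

#' Macroscopic BacNav current
#'
#' Ohmic current law `I = x_level * gbar_1x * m * h * (Vm - E_rev)` in uA/uF.
#' A fallback reversal of +50 mV is used when `e_rev` is `NA` and no host
#' model supplies a Nernst potential.
#'
#' @param vm Membrane potential (mV).
#' @param gates Gate vector from [init_gates()] / [step_gates()].
#' @param params A [bacnav_params()] object.
#' @return Current density (uA/uF); negative is inward.
#' @export
bacnav_current <- function(vm, gates, params) {
  stopifnot(inherits(params, "bacnav_params"))
  check_finite_scalar(vm, "vm")
  e_rev <- if (is.na(params$e_rev)) 50 else params$e_rev
  params$x_level * params$gbar_1x * unname(gates[["m"]]) *
    unname(gates[["h"]]) * (vm - e_rev)
}
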