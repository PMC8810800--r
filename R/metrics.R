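#' Extract action potential features from a voltage trace
#'
#' Computes the AP metrics reported for simulated traces: resting membrane
#' potential (RMP, mean Vm over the 10 ms before the stimulus), AP amplitude
#' (APA = peak Vm - RMP), durations at given repolarization fractions
#' (APD_p, measured from the instant of maximum upstroke velocity to the
#' downward crossing of RMP + (1 - p/100) * APA, with linear interpolation
#' between samples), and the maximum upstroke velocity (central differences,
#' V/s).
#'
#' @param time_ms Sample times (ms), strictly increasing.
#' @param vm Membrane potential samples (mV).
#' @param stim_ms Time of stimulus onset (ms); features are extracted from
#'   the first AP at or after this marker.
#' @param p Repolarization percentages for APD (default 20, 50, 80, 90).
#' @param rmp_window_ms Width of the pre-stimulus window used for RMP.
#' @return A list of class `ap_features`: `rmp`, `apa`, `peak_vm`,
#'   `peak_time`, `dvdt_max` (V/s), `t_dvdt_max`, and `apd` (named vector,
#'   ms).
#' @export
ap_features <- function(time_ms, vm, stim_ms,
                        p = c(20, 50, 80, 90), rmp_window_ms = 10) {
  check_finite(time_ms, "time_ms")
  check_finite(vm, "vm")
  check_finite_scalar(stim_ms, "stim_ms")
  if (length(time_ms) != length(vm)) {
    stop_bacnavsim("bacnavsim_invalid_input", "time and voltage differ in length")
  }
  pre <- time_ms >= (stim_ms - rmp_window_ms) & time_ms < stim_ms
  rmp <- if (any(pre)) mean(vm[pre]) else vm[which.min(abs(time_ms - stim_ms))]
  post <- which(time_ms >= stim_ms)
  if (length(post) < 3L) {
    stop_bacnavsim("bacnavsim_no_ap", "trace contains no samples after the stimulus")
  }
  tp <- time_ms[post]
  vp <- vm[post]
  ipeak <- which.max(vp)
  peak_vm <- vp[ipeak]
  apa <- peak_vm - rmp
  if (apa < 10) {
    stop_bacnavsim("bacnavsim_no_ap",
                   sprintf("no AP elicited (peak - RMP = %.2f mV < 10 mV)", apa))
  }
  # max upstroke velocity by central differences, restricted to the upstroke
  n <- length(vp)
  dvdt <- c(NA, (vp[3:n] - vp[1:(n - 2)]) / (tp[3:n] - tp[1:(n - 2)]), NA)
  up <- seq_len(ipeak)
  imax <- if (any(is.finite(dvdt[up]))) up[which.max(dvdt[up])] else ipeak
  dvdt_max <- max(dvdt[up], 0, na.rm = TRUE)  # mV/ms = V/s
  t_up <- tp[imax]

  apd <- vapply(p, function(pct) {
    thr <- rmp + (1 - pct / 100) * apa
    ii <- which(vp[-n] > thr & vp[-1] <= thr)
    ii <- ii[tp[ii] >= tp[ipeak]]
    if (length(ii) == 0L) return(NA_real_)
    i <- ii[1]
    tc <- tp[i] + (thr - vp[i]) * (tp[i + 1] - tp[i]) / (vp[i + 1] - vp[i])
    tc - t_up
  }, numeric(1))
  names(apd) <- paste0("apd", p)

  structure(list(rmp = rmp, apa = apa, peak_vm = peak_vm,
                 peak_time = tp[ipeak], dvdt_max = dvdt_max,
                 t_dvdt_max = t_up, apd = apd),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf("AP features: RMP %.1f mV, APA %.1f mV, dV/dt max %.0f V/s\n",
              x$rmp, x$apa, x$dvdt_max))
  cat("  APD (ms):", paste(sprintf("%s=%.1f", names(x$apd), x$apd),
                           collapse = ", "), "\n")
  invisible(x)
}
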