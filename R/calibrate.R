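#' Calibrate the 1X BacNav expression level by peak-current matching
#'
#' The 1X expression level is defined as the BacNav conductance whose peak
#' simulated voltage-clamp current equals the peak endogenous Nav1.5 current
#' in the same cell model. Both peaks are taken as the maximum-magnitude
#' signed extremum over the protocol steps (holding -80 mV, 500 ms steps to
#' -50..+50 mV in 10 mV increments, mirroring the experimental patch
#' protocol). The search is a deterministic bisection on the conductance;
#' peak |I_BacNav| is checked to be increasing over the bracket.
#'
#' @param cell A host cell built with [build_cell()]; must have nonzero
#'   endogenous sodium conductance.
#' @param holding,steps,step_ms Clamp protocol (see [voltage_clamp()]).
#' @param tol_pct Relative matching tolerance (%).
#' @param bracket Search bracket for `gbar_1x` (mS/uF).
#' @return A list of class `calibration_report`: `gbar_1x`, `peak_ina_ref`,
#'   `peak_bacnav`, `mismatch_pct`, `protocol`.
#' @export
calibrate_1x <- function(cell, holding = -80, steps = seq(-50, 50, 10),
                         step_ms = 500, tol_pct = 0.1,
                         bracket = c(1e-4, 1e3)) {
  gna <- cell$params[["gNa_scale"]]
  if (is.null(gna) || gna <= 0) {
    stop_bacnavsim("bacnavsim_calibration_undefined",
                   "cell has no endogenous sodium conductance to match")
  }
  iv_ref <- voltage_clamp(cell, holding, steps, step_ms, current = "I_Na")
  ref <- max(abs(iv_ref$peak))
  peak_at <- function(g) {
    probe <- cell
    probe$params[["g_bacnav"]] <- g
    iv <- voltage_clamp(probe, holding, steps, step_ms, current = "I_BacNav")
    max(abs(iv$peak))
  }
  lo <- bracket[1]; hi <- bracket[2]
  p_lo <- peak_at(lo); p_hi <- peak_at(hi)
  if (p_hi <= p_lo) {
    stop_bacnavsim("bacnavsim_search_failure",
                   "peak |I_BacNav| is not increasing over the bracket")
  }
  if (!(p_lo <= ref && ref <= p_hi)) {
    stop_bacnavsim("bacnavsim_search_failure",
                   sprintf("reference peak %.3g uA/uF outside bracket peaks [%.3g, %.3g]",
                           ref, p_lo, p_hi))
  }
  repeat {
    mid <- sqrt(lo * hi)  # bisect in log space: conductance spans decades
    p_mid <- peak_at(mid)
    if (p_mid < ref) lo <- mid else hi <- mid
    if (abs(p_mid - ref) / ref * 100 <= tol_pct || hi / lo < 1 + 1e-6) break
  }
  gbar <- mid
  peak_b <- p_mid
  structure(list(
    gbar_1x = gbar,
    peak_ina_ref = ref,
    peak_bacnav = peak_b,
    mismatch_pct = abs(peak_b - ref) / ref * 100,
    protocol = sprintf("hold %g mV, %g ms steps to [%g..%g] mV", holding,
                       step_ms, min(steps), max(steps)),
    species = cell$species
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %s: gbar_1x = %.4g mS/uF (peak I_Na %.3g, peak I_BacNav %.3g uA/uF, mismatch %.3g %%)\n",
              x$species, x$gbar_1x, x$peak_ina_ref, x$peak_bacnav,
              x$mismatch_pct))
  invisible(x)
}

#' Session-cached 1X conductance for a species
#'
#' Runs [calibrate_1x()] on the baseline cell of the species the first time
#' it is needed and caches the result for the session.
#'
#' @param species `"human"` or `"guineapig"`.
#' @return `gbar_1x` in mS/uF.
#' @export
default_gbar_1x <- function(species) {
  key <- paste0("gbar1x:", species)
  hit <- .bacnavsim_cache[[key]]
  if (!is.null(hit)) return(hit)
  rep <- calibrate_1x(build_cell(species))
  .bacnavsim_cache[[key]] <- rep$gbar_1x
  rep$gbar_1x
}
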