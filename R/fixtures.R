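#' Build the two-variable toy excitable cell
#'
#' A threshold-and-recovery excitable system (Aliev-Panfilov form) mapped
#' onto a voltage-like scale, used as a fast fixture for solver
#' verification: it has a known excitation threshold, an action potential
#' duration checked against a fine-step reference integration, and a cable
#' conduction velocity that scales as the square root of the diffusion
#' coefficient.
#'
#' @param params Named list of overrides for the toy parameters
#'   (`k`, `a`, `eps0`, `mu1`, `mu2`, `t_scale`, `v_rest`, `v_amp`).
#' @param dt Integrator step (ms).
#' @return A `bacnav_cell` of species `"toy"`.
#' @export
make_toy_model <- function(params = list(), dt = 0.01) {
  defaults <- .model_info("toy")$default_params
  p <- modifyList(as.list(defaults), params)
  # documented stable region of the parameterization
  if (p$k < 2 || p$k > 20 || p$a <= 0 || p$a >= 0.5 || p$eps0 <= 0 ||
      p$eps0 > 0.1 || p$mu1 < 0 || p$mu2 <= 0 || p$t_scale <= 0 ||
      p$v_amp <= 0) {
    stop_bacnavsim("bacnavsim_invalid_input",
                   "toy parameters outside the documented stable region")
  }
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop_bacnavsim("bacnavsim_invalid_input",
                   paste("unknown toy parameters:", paste(unknown, collapse = ", ")))
  }
  build_cell("toy", conductances = p, dt = dt)
}

#' Prescribed analytic test fields for the estimator and ECG oracles
#'
#' Emits closed-form activation-time and voltage fields with known ground
#' truth: a planar front (constant speed `v_cm_s` along x), a circular front
#' expanding from the top-left corner, and a travelling Gaussian voltage
#' wave on a 1D fiber for pseudo-ECG quadrature checks.
#'
#' @param v_cm_s Front speed (cm/s).
#' @param nx,ny,dx_cm Grid geometry.
#' @param sigma_cm,duration_ms,dt_ms Gaussian wave shape and sampling.
#' @return A list with `planar` and `circular` activation-time matrices
#'   (ms), and `gaussian` = list(`times`, `x_cm`, `vm`).
#' @export
analytic_fields <- function(v_cm_s = 30, nx = 100, ny = 100, dx_cm = 0.01,
                            sigma_cm = 0.05, duration_ms = 25, dt_ms = 0.5) {
  v_cm_ms <- v_cm_s / 1000
  x <- (seq_len(nx) - 1) * dx_cm
  y <- (seq_len(ny) - 1) * dx_cm
  planar <- matrix(rep(x / v_cm_ms, ny), nx, ny)
  r <- sqrt(outer(x^2, y^2, `+`))
  circular <- r / v_cm_ms
  times <- seq(0, duration_ms, by = dt_ms)
  xf <- (seq_len(nx) - 0.5) * dx_cm
  centers <- 0.25 + v_cm_ms * times
  vm <- -80 + 100 * exp(-outer(centers, xf, `-`)^2 / (2 * sigma_cm^2))
  list(planar = planar, circular = circular,
       gaussian = list(times = times, x_cm = xf, vm = vm, v_cm_s = v_cm_s,
                       sigma_cm = sigma_cm))
}

#' Canonical experiment configurations
#'
#' One configuration per simulated experiment of the study: the human
#' single-cell dose series at normal and 50% reduced sodium conductance,
#' the human 1D cable dose and rescue series, the 2D 15% random-obstacle
#' and 20% vertical-obstacle tissues, and the transmural Brugada cable at
#' none/mild/severe severity crossed with 0/0.2/0.5X expression. These are
#' also shipped as YAML files under `inst/configs/`.
#'
#' @return A named list of config lists accepted by [run_experiment()].
#' @export
canonical_configs <- function() {
  cfgs <- list()
  for (g in c(1, 0.5)) {
    for (x in c(0, 0.5, 1, 2)) {
      tag <- sprintf("cell_human_gna%03d_x%03d", round(100 * g), round(100 * x))
      cfgs[[tag]] <- list(stage = "cell", species = "human", pacing_hz = 1,
                          x_level = x, gNa_scale = g, dt_ms = 0.01,
                          criterion_pct = 0.01, max_beats = 50)
      cfgs[[sub("^cell", "cable", tag)]] <-
        list(stage = "cable", species = "human", x_level = x, gNa_scale = g,
             n_cells = 100, dt_ms = 0.01, ri_kohm_cm = 0.4)
    }
  }
  cfgs$tissue_random15 <- list(stage = "tissue", species = "human",
                               pattern = "random", fraction = 0.15,
                               nx = 100, ny = 100, dx_cm = 0.01,
                               x_level = 0, seed = 1, dt_ms = 0.01)
  cfgs$tissue_vertical20 <- list(stage = "tissue", species = "human",
                                 pattern = "vertical", fraction = 0.20,
                                 strip_length = 10, nx = 100, ny = 100,
                                 dx_cm = 0.01, x_level = 0, seed = 1,
                                 dt_ms = 0.01)
  for (sev in c("none", "mild", "severe")) {
    for (x in c(0, 0.2, 0.5)) {
      cfgs[[sprintf("brugada_%s_x%03d", sev, round(100 * x))]] <-
        list(stage = "brugada", severity = sev, x_level = x,
             pacing_hz = 3.33, dt_ms = 0.01)
    }
  }
  cfgs$calibrate_human <- list(stage = "calibrate", species = "human")
  cfgs
}
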