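#' Read or write an experiment configuration
#'
#' Configurations are flat named lists; YAML (`.yaml`/`.yml`) and JSON
#' (`.json`) files are supported, chosen by extension.
#'
#' @param path File path.
#' @return `read_config()`: the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_bacnavsim("bacnavsim_io", sprintf("config file '%s' not found", path))
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop_bacnavsim("bacnavsim_config_error",
                               sprintf("unsupported config format '.%s'", ext)))
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(config, path),
         json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop_bacnavsim("bacnavsim_config_error",
                        sprintf("unsupported config format '.%s'", ext)))
  invisible(path)
}

config_schema <- list(
  cell = list(required = "species"),
  cable = list(required = "species"),
  tissue = list(required = c("species", "fraction")),
  brugada = list(required = "severity"),
  calibrate = list(required = "species")
)

#' Validate an experiment configuration
#'
#' Checks the stage against the documented schema; violations raise a
#' condition of class `bacnavsim_config_error` naming the offending field.
#'
#' @param config A configuration list.
#' @return The validated config, invisibly unchanged.
#' @export
validate_config <- function(config) {
  if (is.null(config$stage) || !config$stage %in% names(config_schema)) {
    stop_bacnavsim("bacnavsim_config_error",
                   "field 'stage' must be one of cell/cable/tissue/brugada/calibrate")
  }
  sch <- config_schema[[config$stage]]
  for (f in sch$required) {
    if (is.null(config[[f]])) {
      stop_bacnavsim("bacnavsim_config_error",
                     sprintf("field '%s' is required for stage '%s'", f, config$stage))
    }
  }
  if (!is.null(config$fraction) &&
      (config$fraction < 0 || config$fraction >= 1)) {
    stop_bacnavsim("bacnavsim_config_error",
                   "field 'fraction' must be in [0, 1)")
  }
  if (!is.null(config$x_level) && config$x_level < 0) {
    stop_bacnavsim("bacnavsim_config_error", "field 'x_level' must be >= 0")
  }
  if (!is.null(config$pattern) &&
      !config$pattern %in% c("random", "vertical")) {
    stop_bacnavsim("bacnavsim_config_error",
                   "field 'pattern' must be 'random' or 'vertical'")
  }
  invisible(config)
}

#' Run a configured experiment and write its outputs
#'
#' Executes one stage (`cell`, `cable`, `tissue`, `brugada`, `calibrate`),
#' writes CSV/JSON outputs and an append-only run manifest recording the
#' config hash, seeds, package version, per-stage runtime, and the output
#' file registry.
#'
#' @param config A configuration list or a path to a YAML/JSON config.
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic geometry; overrides `config$seed`.
#' @return Invisibly, a list with `summary` and `manifest`.
#' @export
run_experiment <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed
  t0 <- Sys.time()
  outputs <- character()
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE, na = "NA")
    outputs <<- c(outputs, name)
    p
  }
  dt <- config$dt_ms %||% 0.01
  summary <- switch(
    config$stage,
    cell = {
      cell <- build_cell(config$species, x_level = config$x_level %||% 0,
                         gbar_1x = config$gbar_1x,
                         gNa_scale = config$gNa_scale %||% 1, dt = dt)
      pr <- pace_to_equilibrium(cell, config$pacing_hz %||% cell$pacing_hz,
                                criterion_pct = config$criterion_pct %||% 0.01,
                                max_beats = config$max_beats %||% 50)
      ap <- simulate_ap(pr$cell)
      put(ap, "trace.csv")
      f <- attr(ap, "features")
      c(list(stage = "cell", converged = pr$converged, beats = pr$beats),
        if (!is.null(f)) list(rmp_mV = f$rmp, apa_mV = f$apa,
                              apd80_ms = unname(f$apd["apd80"]),
                              dvdt_max_V_s = f$dvdt_max))
    },
    cable = {
      cfg <- cable_config(config$species, x_level = config$x_level %||% 0,
                          gbar_1x = config$gbar_1x,
                          gNa_scale = config$gNa_scale %||% 1,
                          n_cells = config$n_cells %||% 100, dt = dt)
      r <- run_cable(cfg)
      put(data.frame(cell = seq_along(r$act_time_ms),
                     position_cm = r$positions_cm,
                     activation_ms = r$act_time_ms), "activation.csv")
      list(stage = "cable", cv_cm_s = r$cv_cm_s, blocked = r$blocked,
           last_activated = r$last_activated)
    },
    tissue = {
      nx <- config$nx %||% 100; ny <- config$ny %||% 100
      mask <- if ((config$fraction %||% 0) > 0) {
        if ((config$pattern %||% "random") == "vertical") {
          generate_vertical_obstacles(nx, ny, config$fraction,
                                      config$strip_length %||% 10, seed)
        } else {
          generate_random_obstacles(nx, ny, config$fraction, seed)
        }
      } else NULL
      r <- run_tissue(mask, species = config$species,
                      x_level = config$x_level %||% 0,
                      gbar_1x = config$gbar_1x,
                      gNa_scale = config$gNa_scale %||% 1,
                      nx = nx, ny = ny, dx_cm = config$dx_cm %||% 0.01,
                      dt = dt, seed = seed)
      export_activation_map(r, file.path(outdir, "activation_map.csv"))
      outputs <- c(outputs, "activation_map.csv")
      if (!is.null(mask)) {
        put(as.data.frame(ifelse(mask, 1L, 0L)), "obstacle_mask.csv")
      }
      list(stage = "tissue", cv_cm_s = r$cv_cm_s,
           activated_fraction = r$activated_fraction, blocked = r$blocked,
           n_obstacles = r$n_obstacles, seed = seed)
    },
    brugada = {
      cab <- build_transmural_cable(x_level = config$x_level %||% 0,
                                    gbar_1x = config$gbar_1x, dt = dt,
                                    rate_hz = config$pacing_hz %||% 3.33)
      cab <- apply_brugada(cab, config$severity)
      r <- run_transmural(cab)
      put(data.frame(time_ms = r$ecg$times, phi = r$ecg$phi), "ecg.csv")
      for (ly in names(r$aps)) put(r$aps[[ly]], sprintf("ap_%s.csv", ly))
      healthy <- run_transmural(apply_brugada(
        build_transmural_cable(dt = dt,
                               rate_hz = config$pacing_hz %||% 3.33), "none"))
      list(stage = "brugada", severity = config$severity,
           x_level = config$x_level %||% 0,
           ecg_deviation = ecg_deviation(r$ecg, healthy$ecg),
           epi_dome = has_dome(r$aps$epi$time_ms, r$aps$epi$vm_mV))
    },
    calibrate = {
      rep <- calibrate_1x(build_cell(config$species))
      list(stage = "calibrate", species = config$species,
           gbar_1x = rep$gbar_1x, peak_ina_ref = rep$peak_ina_ref,
           peak_bacnav = rep$peak_bacnav, mismatch_pct = rep$mismatch_pct)
    })
  runtime <- as.numeric(Sys.time() - t0, units = "secs")
  spath <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, "summary.json")
  manifest <- list(
    config = config,
    config_hash = config_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("bacnavsim")),
    runtime_s = runtime,
    dt_ms = dt,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mpath <- file.path(outdir, "manifest.json")
  previous <- if (file.exists(mpath)) {
    jsonlite::fromJSON(mpath, simplifyVector = FALSE)
  } else list()
  jsonlite::write_json(c(previous, list(manifest)), mpath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, manifest = manifest))
}

config_hash <- function(config) {
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

#' Export / read an activation map as a CSV grid
#'
#' Activation times are written as an `nx` x `ny` CSV matrix in ms;
#' obstacle and never-activated nodes carry the literal string `NA`.
#'
#' @param map A `tissue_result` or an activation-time matrix.
#' @param path Output CSV path.
#' @return `export_activation_map()`: the path, invisibly;
#'   `read_activation_map()`: the numeric matrix.
#' @export
export_activation_map <- function(map, path) {
  m <- if (inherits(map, "tissue_result")) map$act_map_ms else map
  ok <- tryCatch({
    utils::write.table(m, path, sep = ",", na = "NA",
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_bacnavsim("bacnavsim_io", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' @rdname export_activation_map
#' @export
read_activation_map <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", na.strings = "NA",
                              header = FALSE))
}
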