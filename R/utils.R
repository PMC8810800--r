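# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed error constructor so callers can distinguish failure modes
stop_bacnavsim <- function(class, msg, ...) {
  cnd <- structure(
    class = c(class, "bacnavsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bacnavsim("bacnavsim_invalid_input",
                   sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop_bacnavsim("bacnavsim_invalid_input",
                   sprintf("`%s` must be finite and non-empty", name))
  }
  invisible(x)
}

# run code with a temporarily seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# guarded exponential (arguments clamped to +-700): steep Boltzmann slope
# factors in the BacNav time constants overflow doubles at ordinary voltages
gexp <- function(x) exp(pmin(pmax(x, -700), 700))
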