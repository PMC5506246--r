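# Shared, lazily computed fixtures. The model is deterministic, so tuning
# and the reference simulations are computed once per test run and reused
# across files.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

cached_ref_train <- function() memo("ref_train", reference_fef_train())

cached_grid_result <- function() {
  memo("grid_result",
       brute_force_grid(ref_train = cached_ref_train()))
}

cached_fit <- function() memo("fit", fit_contour_quadratic(cached_grid_result()))

cached_table <- function() {
  memo("table", assign_map_parameters(build_grid(), cached_fit()))
}

cached_config <- function() {
  memo("config", sim_config(params = cached_table()))
}

# one trial per (amplitude, lateral) pair
cached_trial <- function(amplitude, lateral = TRUE) {
  key <- sprintf("trial_%g_%d", amplitude, lateral)
  memo(key, {
    cfg <- cached_config()
    cfg$amplitude <- amplitude
    cfg$lateral <- lateral
    simulate_trial(cfg)
  })
}

cached_kappa <- function() memo("kappa", calibrate_kappa(cached_config())$kappa)
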