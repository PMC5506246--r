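#' Simulation configuration
#'
#' Assembles all parameter sets of a two-layer trial: the motor-map
#' constants, input-current parameters, the FEF and SC AdEx presets,
#' synapse constants, Mexican-hat lateral weights, and the per-neuron
#' SC tuning table (`tau_q(u)`, `w_ff(u)`).
#'
#' The model is fully deterministic: the optional `seed` is used only by
#' the genetic algorithm in the lateral-weight tuning and is recorded here
#' for provenance.
#'
#' @param amplitude Saccade-target amplitude (degrees).
#' @param dt Integration step (ms). The network is integrated by forward
#'   Euler; 0.01 ms reproduces the reference step size, and the tests
#'   verify convergence under refinement.
#' @param horizon Trial duration (ms). With the default input parameters
#'   the external current has decayed below 1% of its peak by 350 ms and
#'   all bursts complete well before 300 ms.
#' @param lateral Enable the Mexican-hat lateral connections?
#' @param map,input,fef,sc,syn,hat Component parameter objects.
#' @param params An [sc_parameter_table()] (per-neuron `tau_q`, `w_ff`);
#'   `NULL` means it must be supplied before [simulate_trial()].
#' @param spike_guard Per-neuron spike-count limit; exceeding it aborts the
#'   run with a diagnostic (protects against unbalanced lateral weights).
#' @param seed Optional integer, recorded for provenance.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(amplitude = 21, dt = 0.01, horizon = 300,
                       lateral = TRUE, map = map_constants(),
                       input = input_params(),
                       fef = adex_params("FEF"), sc = adex_params("SC"),
                       syn = synapse_params(), hat = mexican_hat_params(),
                       params = NULL, spike_guard = 200L, seed = NULL) {
  stopifnot(dt > 0, horizon > 0, spike_guard > 0)
  structure(list(amplitude = amplitude, dt = dt, horizon = horizon,
                 lateral = lateral, map = map, input = input, fef = fef,
                 sc = sc, syn = syn, hat = hat, params = params,
                 spike_guard = as.integer(spike_guard), seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trial configuration: target", x$amplitude, "deg, dt =", x$dt,
      "ms, horizon =", x$horizon, "ms, lateral",
      if (x$lateral) "on" else "off", "\n")
  cat("  SC tuning table:",
      if (is.null(x$params)) "not set" else "per-neuron tau_q / w_ff", "\n")
  invisible(x)
}

#' Run one two-layer trial
#'
#' Drives the FEF layer with the external current for the configured
#' target, propagates spikes to the SC layer through one-to-one
#' feedforward synapses and (optionally) the Mexican-hat lateral matrices,
#' and records every spike. Deterministic: identical configurations give
#' bit-identical spike sets.
#'
#' @param config A [sim_config()]; `config$params` must be set (see
#'   [tune_sc_neurons()] / [assign_map_parameters()]).
#' @return An object of class `spike_train_set`: per-neuron spike-time
#'   lists `fef` and `sc`, the `grid`, the central-neuron index `center`,
#'   and the `config`.
#' @export
simulate_trial <- function(config) {
  if (is.null(config$params))
    stop("config$params is not set; build the SC tuning table first ",
         "(see tune_sc_neurons())")
  grid <- build_grid(config$map)
  n <- length(grid$positions)
  if (nrow(config$params) != n)
    stop("tuning table covers ", nrow(config$params),
         " neurons but the grid has ", n)
  uT <- afferent_position(config$amplitude, config$map)
  W <- mexican_hat_weights(grid, config$hat)
  raw <- network_sim_cpp(grid$positions, uT,
                         c(config$input$I0, config$input$sigma_pop,
                           config$input$beta, config$input$gamma),
                         adex_param_vector(config$fef),
                         adex_param_vector(config$sc),
                         config$params$tau_q, config$params$w_ff,
                         c(config$syn$E_e, config$syn$E_i,
                           config$syn$tau_e, config$syn$tau_i),
                         W$W_exc, W$W_inh, isTRUE(config$lateral),
                         config$dt, config$horizon, config$spike_guard)
  structure(list(fef = raw$fef, sc = raw$sc, grid = grid,
                 center = central_neuron(grid, config$amplitude),
                 config = config),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  nf <- sum(lengths(x$fef)); ns <- sum(lengths(x$sc))
  cat("Spike trains for a", x$config$amplitude, "deg target:", nf,
      "FEF spikes,", ns, "SC spikes\n")
  cat("  central SC neuron", x$center, "emitted",
      length(x$sc[[x$center]]), "spikes\n")
  invisible(x)
}

#' Spike counts per neuron
#'
#' @param spikes A [simulate_trial()] result.
#' @param layer `"sc"` or `"fef"`.
#' @return Integer vector of per-neuron spike counts.
#' @export
spike_counts <- function(spikes, layer = c("sc", "fef")) {
  layer <- match.arg(layer)
  lengths(spikes[[layer]])
}

#' Spike events as a table
#'
#' Flattens a spike-train set into a long event table, the package's
#' plain-text interchange format (one row per spike).
#'
#' @param spikes A [simulate_trial()] result.
#' @return A data.frame with columns `layer`, `neuron`, `time_ms`.
#' @export
spike_events <- function(spikes) {
  build <- function(lst, layer) {
    cnt <- lengths(lst)
    data.frame(layer = rep(layer, sum(cnt)),
               neuron = rep(seq_along(lst), cnt),
               time_ms = as.numeric(unlist(lst, use.names = FALSE)))
  }
  rbind(build(spikes$fef, "fef"), build(spikes$sc, "sc"))
}
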