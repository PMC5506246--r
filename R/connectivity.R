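#' Synapse parameters
#'
#' Conductance-based synapse constants for the SC layer. Excitatory and
#' inhibitory conductances jump instantly by the synaptic weight on each
#' presynaptic spike and decay exponentially otherwise; the synaptic
#' current is driving-force weighted:
#' `I_syn = g_exc (E_e - V) + g_inh (E_i - V)`.
#'
#' @param E_e,E_i Excitatory/inhibitory reversal potentials (mV).
#' @param tau_e,tau_i Excitatory/inhibitory conductance decay constants (ms).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(E_e = 0, E_i = -80, tau_e = 5, tau_i = 10) {
  stopifnot(tau_e > 0, tau_i > 0, E_e > E_i)
  structure(list(E_e = E_e, E_i = E_i, tau_e = tau_e, tau_i = tau_i),
            class = "synapse_params")
}

#' Mexican-hat lateral-connectivity parameters
#'
#' Lateral connection strengths between SC neurons are two Gaussians of
#' anatomical distance: strong short-range excitation
#' (`w_exc * exp(-d^2 / (2 sigma_exc^2))`) and weak long-range inhibition
#' (`w_inh * exp(-d^2 / (2 sigma_inh^2))`), whose difference is a Mexican
#' hat implementing a soft winner-take-all. The hat regime requires
#' `w_exc > w_inh` together with `sigma_inh > sigma_exc`; parameter sets
#' outside that regime are deliberately constructible (the tuning scans
#' explore them), so the constructor only enforces positivity. Strict
#' validation is applied when a configuration file is loaded.
#'
#' @param w_exc,w_inh Excitatory/inhibitory scaling factors (pS).
#' @param sigma_exc,sigma_inh Gaussian ranges (mm).
#' @return An object of class `mexican_hat_params`.
#' @export
mexican_hat_params <- function(w_exc = 160, w_inh = 50,
                               sigma_exc = 0.4, sigma_inh = 1.2) {
  stopifnot(w_exc >= 0, w_inh >= 0, sigma_exc > 0, sigma_inh > 0)
  structure(list(w_exc = w_exc, w_inh = w_inh,
                 sigma_exc = sigma_exc, sigma_inh = sigma_inh),
            class = "mexican_hat_params")
}

#' @export
print.mexican_hat_params <- function(x, ...) {
  cat("Mexican-hat lateral connectivity: w_exc =", x$w_exc, "pS (sigma",
      x$sigma_exc, "mm ), w_inh =", x$w_inh, "pS (sigma", x$sigma_inh,
      "mm )\n")
  invisible(x)
}

#' Lateral weight matrices
#'
#' Builds the excitatory and inhibitory lateral strength matrices from the
#' pairwise distances on the grid. Self-projections are omitted (zero
#' diagonal) to prevent the activity from blowing up. Entries are returned
#' in nS (inputs are in pS) so they combine directly with the conductance
#' state.
#'
#' @param grid A [build_grid()] object.
#' @param hat A [mexican_hat_params()] object.
#' @return List with symmetric, nonnegative, zero-diagonal matrices
#'   `W_exc` and `W_inh` (nS).
#' @export
mexican_hat_weights <- function(grid, hat = mexican_hat_params()) {
  if (!inherits(hat, "mexican_hat_params")) stop("`hat` must be mexican_hat_params")
  d <- outer(grid$positions, grid$positions, "-")
  W_exc <- hat$w_exc * 1e-3 * exp(-d^2 / (2 * hat$sigma_exc^2))
  W_inh <- hat$w_inh * 1e-3 * exp(-d^2 / (2 * hat$sigma_inh^2))
  diag(W_exc) <- 0
  diag(W_inh) <- 0
  list(W_exc = W_exc, W_inh = W_inh)
}

#' Synaptic current from the conductance state
#'
#' @param V Membrane potential(s), mV.
#' @param g_exc,g_inh Conductances, nS.
#' @param syn A [synapse_params()] object.
#' @return Current in pA.
#' @export
synaptic_current <- function(V, g_exc, g_inh, syn = synapse_params()) {
  g_exc * (syn$E_e - V) + g_inh * (syn$E_i - V)
}

#' Advance the SC conductance state by one step
#'
#' Reference (pure R) update used by the tests against the compiled
#' network integrator. Conductances decay by the exact exponential factor
#' over `dt`; feedforward spikes at neuron `n` add `w_ff[n]` to `g_exc[n]`
#' (one-to-one topography); each lateral SC spike at neuron `i` adds row
#' `i` of `W_exc` / `W_inh` to the excitatory / inhibitory conductances of
#' all other neurons.
#'
#' @param g_exc,g_inh Conductance vectors (nS).
#' @param dt Time step (ms).
#' @param syn A [synapse_params()] object.
#' @param fef_spiked Logical vector: which FEF partners spiked.
#' @param sc_spiked Logical vector: which SC neurons spiked (previous step).
#' @param w_ff Feedforward weight vector (nS).
#' @param W Optional list with `W_exc`, `W_inh` from
#'   [mexican_hat_weights()]; omit for a purely feedforward network.
#' @return List with updated `g_exc`, `g_inh`.
#' @export
conductance_step <- function(g_exc, g_inh, dt, syn = synapse_params(),
                             fef_spiked = NULL, sc_spiked = NULL,
                             w_ff = NULL, W = NULL) {
  stopifnot(dt > 0)
  if (!is.null(fef_spiked) && any(fef_spiked))
    g_exc <- g_exc + ifelse(fef_spiked, w_ff, 0)
  if (!is.null(W) && !is.null(sc_spiked) && any(sc_spiked)) {
    idx <- which(sc_spiked)
    g_exc <- g_exc + colSums(W$W_exc[idx, , drop = FALSE])
    g_inh <- g_inh + colSums(W$W_inh[idx, , drop = FALSE])
  }
  list(g_exc = g_exc * exp(-dt / syn$tau_e),
       g_inh = g_inh * exp(-dt / syn$tau_i))
}
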