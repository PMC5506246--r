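#' AdEx neuron parameters
#'
#' Parameters of the adaptive exponential integrate-and-fire (AdEx) neuron,
#' with two named presets: `"FEF"` for the input layer (regular spiking:
#' reset below threshold) and `"SC"` for the collicular layer (intrinsic
#' bursting: the reset potential `V_r = -45` mV lies above the spike
#' initiation threshold `V_T = -50` mV, so after each reset the exponential
#' term re-drives the cell and bursts terminate only through the
#' accumulated adaptation current `q`).
#'
#' The membrane obeys
#' `C dV/dt = -g_L (V - E_L) + g_L eta exp((V - V_T)/eta) - q + I_inp`,
#' `tau_q dq/dt = a (V - E_L) - q`,
#' with reset `V -> V_r`, `q -> q + b` whenever `V` reaches the practical
#' spiking threshold `V_peak`.
#'
#' @param preset `"SC"` or `"FEF"`.
#' @param ... Named overrides of individual parameters (e.g. `tau_q = 40`).
#' @return An object of class `adex_params` with fields `C` (pF), `g_L`
#'   (nS), `E_L`, `V_T`, `V_peak`, `V_r`, `eta` (mV), `a` (nS), `b` (pA),
#'   `tau_q` (ms).
#' @export
adex_params <- function(preset = c("SC", "FEF"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    FEF = list(C = 50, g_L = 2, E_L = -70, V_T = -50, V_peak = -30,
               eta = 2, a = 0, b = 60, V_r = -55, tau_q = 30),
    SC  = list(C = 280, g_L = 10, E_L = -70, V_T = -50, V_peak = -30,
               eta = 2, a = 4, b = 80, V_r = -45, tau_q = 30))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown AdEx parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$C > 0, p$g_L > 0, p$eta > 0, p$tau_q > 0, p$V_peak > p$V_T)
  structure(c(p, list(preset = preset)), class = "adex_params")
}

#' @export
print.adex_params <- function(x, ...) {
  cat("AdEx parameters (", x$preset, " preset): C = ", x$C, " pF, g_L = ",
      x$g_L, " nS, tau_q = ", x$tau_q, " ms\n", sep = "")
  cat("  E_L =", x$E_L, "V_T =", x$V_T, "V_peak =", x$V_peak,
      "V_r =", x$V_r, "eta =", x$eta, "(mV); a =", x$a, "nS, b =", x$b,
      "pA\n")
  invisible(x)
}

# fixed-order numeric vector consumed by the C++ integrators
adex_param_vector <- function(p) {
  c(p$C, p$g_L, p$E_L, p$V_T, p$V_peak, p$eta, p$a, p$b, p$V_r, p$tau_q)
}

#' One forward-Euler step of the AdEx equations
#'
#' Reference (pure R) single-step update used by the tests as an
#' independent check of the compiled integrator: state update first, then
#' threshold test, then reset. The exponential argument is clamped at
#' `(V_peak - V_T)/eta + 5` so the update never overflows; past that point
#' the spike fires regardless, so the clamp cannot change spike times.
#'
#' @param state Named list or vector with `V` (mV) and `q` (pA).
#' @param I_inp Input current (pA).
#' @param p An [adex_params()] object.
#' @param dt Time step (ms).
#' @return List with `V`, `q` and logical `spiked`.
#' @export
adex_step <- function(state, I_inp, p, dt) {
  if (!all(is.finite(c(state$V, state$q, I_inp, dt))) || dt <= 0)
    stop("adex_step: inputs must be finite and dt > 0")
  arg <- min((state$V - p$V_T) / p$eta, (p$V_peak - p$V_T) / p$eta + 5)
  dV <- (-p$g_L * (state$V - p$E_L) + p$g_L * p$eta * exp(arg) -
           state$q + I_inp) / p$C
  dq <- (p$a * (state$V - p$E_L) - state$q) / p$tau_q
  V <- state$V + dt * dV
  q <- state$q + dt * dq
  spiked <- V >= p$V_peak
  if (spiked) {
    V <- p$V_r
    q <- q + p$b
  }
  list(V = V, q = q, spiked = spiked)
}

#' Integrate a single AdEx neuron
#'
#' Drives one neuron either by a presynaptic spike train through an
#' excitatory conductance-based synapse (each presynaptic spike increments
#' `g_exc` by `w` nS; `g_exc` decays with `tau_e` toward 0 and the current
#' is `g_exc * (E_e - V)`), by an externally supplied current series, or
#' both. Integration is forward Euler at step `dt`; deterministic.
#'
#' @param p An [adex_params()] object.
#' @param dt Time step (ms).
#' @param horizon Simulated duration (ms).
#' @param pre_spikes Optional numeric vector of presynaptic spike times (ms).
#' @param w Synaptic weight for `pre_spikes` (nS).
#' @param syn A [synapse_params()] object (only `tau_e`, `E_e` are used).
#' @param I_ext Optional current series (pA), one value per step.
#' @param traces If `TRUE`, also return `time`, `V`, `q`, `g_exc` traces.
#' @return List with `spikes` (strictly increasing spike times, ms) and,
#'   if requested, the state traces.
#' @export
integrate_neuron <- function(p, dt = 0.01, horizon = 300,
                             pre_spikes = NULL, w = NULL,
                             syn = synapse_params(), I_ext = NULL,
                             traces = FALSE) {
  stopifnot(dt > 0, horizon > 0)
  if (!is.null(pre_spikes) && is.null(w))
    stop("a presynaptic spike train requires a weight `w`")
  n_steps <- round(horizon / dt)
  if (!is.null(I_ext) && length(I_ext) != n_steps)
    stop("I_ext must have one value per step (", n_steps, ")")
  adex_integrate_cpp(adex_param_vector(p), dt, horizon,
                     if (is.null(I_ext)) numeric(0) else I_ext,
                     if (is.null(pre_spikes)) numeric(0) else
                       as.numeric(pre_spikes),
                     if (is.null(w)) 0 else w,
                     syn$tau_e, syn$E_e, traces)
}
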