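#' External input-current parameters
#'
#' The saccade target is presented to the input (FEF) layer as a
#' translation-invariant spatial-temporal current: a Gaussian in map
#' position centred on the afferent image `u_T` of the target, scaling a
#' gamma-shaped temporal profile
#' `I0 * exp(-(u_n - u_T)^2 / (2 sigma_pop^2)) * t^gamma * exp(-beta t)`
#' with `t` in ms. With the defaults the temporal factor peaks at
#' `gamma / beta = 60` ms and is effectively extinguished by 350 ms.
#'
#' @param sigma_pop Width of the recruited population (mm).
#' @param beta Temporal decay rate (1/ms); sets the burst duration.
#' @param gamma Dimensionless exponent; sets skewness and peak of the burst.
#' @param I0 Scaling constant (pA).
#' @return An object of class `input_params`.
#' @export
input_params <- function(sigma_pop = 0.5, beta = 0.03, gamma = 1.8, I0 = 3) {
  stopifnot(sigma_pop > 0, beta > 0, gamma > 0, I0 >= 0)
  structure(list(sigma_pop = sigma_pop, beta = beta, gamma = gamma, I0 = I0),
            class = "input_params")
}

#' External current to an input-layer neuron
#'
#' @param u_n Neuron position(s), mm.
#' @param u_T Afferent image of the target, mm.
#' @param t Time(s) since trial onset, ms; must be nonnegative.
#' @param params An [input_params()] object.
#' @return Current in pA (vectorized over `u_n` and `t` with recycling).
#' @export
external_current <- function(u_n, u_T, t, params = input_params()) {
  if (any(t < 0)) stop("time `t` must be nonnegative")
  spatial <- exp(-(u_n - u_T)^2 / (2 * params$sigma_pop^2))
  temporal <- ifelse(t > 0, t^params$gamma * exp(-params$beta * t), 0)
  params$I0 * spatial * temporal
}

#' Input-current profile over the grid and a time axis
#'
#' @param grid A [build_grid()] object.
#' @param r Target amplitude (degrees).
#' @param times Time axis, ms.
#' @param params An [input_params()] object.
#' @return Matrix (neurons x times) of currents, pA.
#' @export
current_profile <- function(grid, r, times, params = input_params()) {
  uT <- afferent_position(r, grid$map)
  outer(grid$positions, times,
        function(u, t) external_current(u, uT, t, params))
}
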