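#' Motor-map constants
#'
#' Constants of the log-polar gaze motor map of the monkey superior
#' colliculus, restricted to the horizontal meridian (direction 0 deg).
#' The afferent mapping places a saccade target of amplitude `r` (degrees)
#' at `u = B_u * log((r + A) / A)` mm from the rostral pole; the efferent
#' mapping assigns each site a fixed "minivector" contribution per spike
#' (see [efferent_minivector()]).
#'
#' @param B_u Scale along the rostral-caudal axis u (mm).
#' @param B_v Scale along the direction axis v (mm/rad). Carried for the
#'   full 2-D formula, which the 1-D model always evaluates at `v = 0`.
#' @param A Foveal offset of the logarithmic mapping (degrees).
#' @param kappa Efferent scaling factor (degrees per spike). Left `NA` by
#'   default: it is calibrated at run time against a 21-degree saccade
#'   (see [calibrate_kappa()]), not fixed a priori.
#' @param map_length Length of the modelled map midline (mm).
#' @param n_neurons Number of neurons per layer.
#' @return An object of class `map_constants`.
#' @examples
#' m <- map_constants()
#' afferent_position(21, m)
#' @export
map_constants <- function(B_u = 1.4, B_v = 1.8, A = 3, kappa = NA_real_,
                          map_length = 5, n_neurons = 200L) {
  stopifnot(B_u > 0, B_v > 0, A > 0, map_length > 0, n_neurons >= 2)
  structure(list(B_u = B_u, B_v = B_v, A = A, kappa = kappa,
                 map_length = map_length, n_neurons = as.integer(n_neurons)),
            class = "map_constants")
}

#' @export
print.map_constants <- function(x, ...) {
  cat("Motor-map constants: B_u =", x$B_u, "mm, B_v =", x$B_v,
      "mm/rad, A =", x$A, "deg\n")
  cat("  map length", x$map_length, "mm,", x$n_neurons, "neurons/layer,",
      "kappa =", format(x$kappa), "\n")
  invisible(x)
}

#' Afferent mapping: target amplitude to map position
#'
#' `u = B_u * log((r + A) / A)`. Monotone increasing; zero amplitude maps to the
#' rostral pole `u = 0`.
#'
#' @param r Saccade amplitude(s), degrees; must be nonnegative.
#' @param map A [map_constants()] object.
#' @return Map position(s) in mm.
#' @export
afferent_position <- function(r, map = map_constants()) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("saccade amplitude `r` must be finite and nonnegative")
  map$B_u * log((r + map$A) / map$A)
}

#' Inverse afferent mapping: map position to amplitude
#'
#' Analytic inverse: `A * (exp(u / B_u) - 1)` degrees.
#'
#' @param u Map position(s), mm.
#' @param map A [map_constants()] object.
#' @return Saccade amplitude(s), degrees.
#' @export
inverse_afferent <- function(u, map = map_constants()) {
  map$A * (exp(u / map$B_u) - 1)
}

#' Efferent minivector of a map site
#'
#' The fixed movement contribution (degrees) of one spike emitted at map
#' position `(u, v)`:
#' horizontal `kappa * A * (exp(u/B_u) * cos(v/B_v) - 1)` and vertical
#' `kappa * A * exp(u/B_u) * sin(v/B_v)`. The 1-D model always evaluates at
#' `v = 0`, where the vertical component vanishes exactly and the
#' horizontal component is the inverse afferent mapping scaled by `kappa`.
#'
#' @param u,v Map coordinates (mm). `v` defaults to 0.
#' @param map A [map_constants()] object.
#' @param kappa Efferent scaling factor; defaults to `map$kappa`.
#' @return A two-column matrix (horizontal, vertical), degrees per spike.
#' @export
efferent_minivector <- function(u, v = 0, map = map_constants(),
                                kappa = map$kappa) {
  if (is.na(kappa)) stop("kappa is not set; calibrate it first")
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  eu <- exp(u / map$B_u)
  cbind(horizontal = kappa * map$A * (eu * cos(v / map$B_v) - 1),
        vertical   = kappa * map$A * eu * sin(v / map$B_v))
}

#' Discrete neuron grid on the map midline
#'
#' Neurons are uniformly distributed on the map midline. The default
#' convention is endpoint-inclusive: `u_n = map_length * n / (n_neurons - 1)`
#' for `n = 0 .. n_neurons - 1`, so the rostral pole (0 deg) and the caudal
#' end of the amplitude range are exactly representable. A cell-centered
#' convention is available via `convention = "center"`.
#'
#' @param map A [map_constants()] object.
#' @param convention `"endpoint"` (default) or `"center"`.
#' @return An object of class `motor_map_grid` with elements `positions`
#'   (mm, strictly increasing) and `map`.
#' @export
build_grid <- function(map = map_constants(),
                       convention = c("endpoint", "center")) {
  convention <- match.arg(convention)
  n <- map$n_neurons
  positions <- switch(convention,
    endpoint = map$map_length * (seq_len(n) - 1) / (n - 1),
    center   = map$map_length * (seq_len(n) - 0.5) / n)
  structure(list(positions = positions, map = map, convention = convention),
            class = "motor_map_grid")
}

#' @export
print.motor_map_grid <- function(x, ...) {
  cat("Motor-map grid:", length(x$positions), "neurons on [0,",
      x$map$map_length, "] mm (", x$convention, "convention ),",
      "spacing", format(diff(x$positions[1:2]), digits = 4), "mm\n")
  invisible(x)
}

#' Index of the central neuron for a target amplitude
#'
#' The central neuron of the recruited population is the cell whose map
#' position is nearest to the afferent image of the target; ties are broken
#' toward the rostral pole (smaller u).
#'
#' @param grid A [build_grid()] object.
#' @param r Target amplitude (degrees).
#' @return 1-based neuron index.
#' @export
central_neuron <- function(grid, r) {
  uT <- afferent_position(r, grid$map)
  d <- abs(grid$positions - uT)
  which(d <= min(d) + 1e-12)[1]
}

#' Neurons within the analysis radius of the population center
#'
#' @param grid A [build_grid()] object.
#' @param r Target amplitude (degrees).
#' @param radius Distance from the population center (mm); the default
#'   0.65 mm is the radius beyond which firing rates drop to zero.
#' @return Integer vector of neuron indices (includes the center).
#' @export
recruited_population <- function(grid, r, radius = 0.65) {
  center_u <- grid$positions[central_neuron(grid, r)]
  which(abs(grid$positions - center_u) <= radius + 1e-12)
}
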