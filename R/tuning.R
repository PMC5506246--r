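#' Reference FEF spike train
#'
#' The spike train of the most active input-layer neuron: a single FEF
#' AdEx neuron placed exactly at the afferent image of the target
#' (distance 0, so the spatial Gaussian is 1). Because the input is
#' translation invariant and FEF neurons are identical, this train is the
#' same for every target amplitude; it is the drive used by the
#' single-neuron brute-force grid.
#'
#' @param config A [sim_config()] (tuning table not required).
#' @return Numeric vector of spike times (ms).
#' @export
reference_fef_train <- function(config = sim_config()) {
  n_steps <- round(config$horizon / config$dt)
  t <- (seq_len(n_steps) - 1) * config$dt
  I <- external_current(0, 0, t, config$input)
  integrate_neuron(config$fef, config$dt, config$horizon, I_ext = I)$spikes
}

#' Brute-force single-neuron parameter grid
#'
#' Drives single SC-preset AdEx neurons with the reference FEF spike train
#' for every combination of adaptation time constant `tau_q` and
#' feedforward weight `w`, recording the burst spike count and the peak
#' firing rate (8-ms kernel spike density). Higher `w` and lower `tau_q`
#' give more spikes and higher peak rates.
#'
#' @param tau_values Adaptation time constants to probe (ms).
#' @param w_values Feedforward weights to probe (nS).
#' @param ref_train Reference FEF spike train ([reference_fef_train()]).
#' @param config A [sim_config()] supplying the SC preset, synapse
#'   constants, `dt` and `horizon`.
#' @param rate_kernel Kernel width for the peak-rate surface (ms).
#' @return An object of class `grid_result`: `tau_q`, `w`, and matrices
#'   `n_spikes`, `peak_rate` (tau_q rows x w columns).
#' @export
brute_force_grid <- function(tau_values = seq(10, 80, by = 2),
                             w_values = seq(5, 16, by = 0.25),
                             ref_train = reference_fef_train(config),
                             config = sim_config(), rate_kernel = 8) {
  n_spikes <- matrix(NA_real_, length(tau_values), length(w_values))
  peak <- matrix(NA_real_, length(tau_values), length(w_values))
  for (i in seq_along(tau_values)) {
    p <- adex_params("SC", tau_q = tau_values[i])
    for (j in seq_along(w_values)) {
      spk <- integrate_neuron(p, config$dt, config$horizon,
                              pre_spikes = ref_train, w = w_values[j],
                              syn = config$syn)$spikes
      n_spikes[i, j] <- length(spk)
      peak[i, j] <- peak_rate(spike_density(spk, rate_kernel))
    }
  }
  structure(list(tau_q = tau_values, w = w_values, n_spikes = n_spikes,
                 peak_rate = peak, ref_train = ref_train),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("Brute-force grid:", length(x$tau_q), "tau_q x", length(x$w),
      "w values; spike counts", min(x$n_spikes), "-", max(x$n_spikes), "\n")
  invisible(x)
}

#' Iso-spike-count contour points
#'
#' For each `tau_q` of the grid, the representative weight on the
#' `target_spikes` contour: the midpoint of the interval of `w` values
#' whose burst has exactly `target_spikes` spikes (spike count is a step
#' function of `w`, so the contour is a band one or more grid columns
#' wide). `tau_q` values without any such `w` are dropped.
#'
#' @param grid_result A [brute_force_grid()] result.
#' @param target_spikes Target burst spike count, default 20.
#' @return A data.frame with `tau_q` and `w`.
#' @export
contour_points <- function(grid_result, target_spikes = 20) {
  pts <- lapply(seq_along(grid_result$tau_q), function(i) {
    hit <- which(grid_result$n_spikes[i, ] == target_spikes)
    if (!length(hit)) return(NULL)
    data.frame(tau_q = grid_result$tau_q[i],
               w = mean(range(grid_result$w[hit])))
  })
  do.call(rbind, pts)
}

#' Quadratic fit of the iso-spike-count contour
#'
#' Least-squares second-order polynomial `w(tau_q)` through the contour
#' points of the brute-force grid.
#'
#' @param grid_result A [brute_force_grid()] result (or a data.frame of
#'   contour points with columns `tau_q`, `w`).
#' @param target_spikes Target burst spike count, default 20.
#' @return An object of class `contour_fit`: `coef` (intercept, linear,
#'   quadratic), `points`, `residual_rmse`, and `predict(tau_q)` via
#'   [predict.contour_fit()].
#' @export
fit_contour_quadratic <- function(grid_result, target_spikes = 20) {
  pts <- if (is.data.frame(grid_result)) grid_result
         else contour_points(grid_result, target_spikes)
  if (is.null(pts) || nrow(pts) < 3)
    stop("need at least 3 contour points for a quadratic fit")
  fit <- stats::lm(w ~ tau_q + I(tau_q^2), data = pts)
  structure(list(coef = unname(stats::coef(fit)), points = pts,
                 residual_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 target_spikes = target_spikes),
            class = "contour_fit")
}

#' @export
predict.contour_fit <- function(object, tau_q, ...) {
  object$coef[1] + object$coef[2] * tau_q + object$coef[3] * tau_q^2
}

#' @export
print.contour_fit <- function(x, ...) {
  cat("Iso-", x$target_spikes, "-spike contour fit: w(tau_q) = ",
      format(x$coef[1], digits = 4), " + ", format(x$coef[2], digits = 4),
      " tau_q + ", format(x$coef[3], digits = 4), " tau_q^2  (rmse ",
      format(x$residual_rmse, digits = 3), " nS, ", nrow(x$points),
      " points)\n", sep = "")
  invisible(x)
}

#' Per-neuron SC tuning table
#'
#' Builds the location-dependent SC parameters: the adaptation time
#' constant decreases linearly along the map from `tau_range[1]` at the
#' rostral pole to `tau_range[2]` at the caudal end (80 to 10 ms by
#' default), and the feedforward weight follows the fitted
#' iso-spike-count quadratic, so that every neuron emits the same number
#' of spikes for its optimal saccade while peak rate and burst duration
#' vary systematically with map position.
#'
#' @param grid A [build_grid()] object.
#' @param fit A [fit_contour_quadratic()] result.
#' @param tau_range `c(rostral, caudal)` adaptation time constants (ms).
#' @return An [sc_parameter_table()]: data.frame with `u`, `tau_q`, `w_ff`.
#' @export
assign_map_parameters <- function(grid, fit, tau_range = c(80, 10)) {
  u <- grid$positions
  tau_q <- tau_range[1] +
    (tau_range[2] - tau_range[1]) * u / grid$map$map_length
  w_ff <- predict(fit, tau_q)
  if (any(!is.finite(w_ff)) || any(w_ff <= 0))
    stop("fitted feedforward weights are not all positive and finite")
  sc_parameter_table(u, tau_q, w_ff)
}

#' Construct an SC tuning table
#'
#' @param u Neuron positions (mm).
#' @param tau_q Per-neuron adaptation time constants (ms).
#' @param w_ff Per-neuron feedforward weights (nS).
#' @return A data.frame of class `sc_parameter_table`.
#' @export
sc_parameter_table <- function(u, tau_q, w_ff) {
  stopifnot(length(u) == length(tau_q), length(u) == length(w_ff),
            all(tau_q > 0), all(w_ff > 0))
  structure(data.frame(u = u, tau_q = tau_q, w_ff = w_ff),
            class = c("sc_parameter_table", "data.frame"))
}

#' Full SC neuron tuning pipeline
#'
#' Runs the brute-force grid with the reference FEF train, fits the
#' 20-spike contour with a quadratic, and assigns the per-neuron
#' parameters along the map. This is the procedure that gives the model
#' its motor-map gradient (peak rates decreasing and burst durations
#' increasing from rostral to caudal).
#'
#' @param config A [sim_config()].
#' @param tau_values,w_values Grid axes (see [brute_force_grid()]).
#' @param target_spikes Burst spike-count target, default 20.
#' @param tau_range Linear `tau_q` assignment along the map, default
#'   `c(80, 10)` ms.
#' @return List with `grid_result`, `fit`, and the tuning `table`.
#' @export
tune_sc_neurons <- function(config = sim_config(),
                            tau_values = seq(10, 80, by = 2),
                            w_values = seq(5, 16, by = 0.25),
                            target_spikes = 20, tau_range = c(80, 10)) {
  gr <- brute_force_grid(tau_values, w_values,
                         ref_train = reference_fef_train(config),
                         config = config)
  fit <- fit_contour_quadratic(gr, target_spikes)
  grid <- build_grid(config$map)
  list(grid_result = gr, fit = fit,
       table = assign_map_parameters(grid, fit, tau_range))
}

#' Closed-form peak-rate model
#'
#' Peak firing rate of the central cell as a function of saccade
#' amplitude in the rate-based description the network is tuned against:
#' `F_peak(r) = F0 / sqrt(1 + beta * r)` with `F0 = 800` spikes/s and
#' `beta = 0.07` per degree.
#'
#' @param r Saccade amplitude(s), degrees (nonnegative).
#' @param F0 Rate at zero amplitude, spikes/s.
#' @param beta Amplitude sensitivity, 1/degree.
#' @return Peak rate(s), spikes/s.
#' @export
rate_model_peak <- function(r, F0 = 800, beta = 0.07) {
  stopifnot(all(r >= 0))
  F0 / sqrt(1 + beta * r)
}

#' Weighted-RMSE fitness score
#'
#' Combines the three error components of the lateral-weight search into
#' one score: `0.1 * RMSE(peak rates) + 10 * RMSE(spike counts) +
#' 1000 * RMSE(correlation deviations)`. The weights bring the three
#' terms to comparable ranges (peak rates span roughly 750 to 430
#' spikes/s, counts sit near 20, correlations just below 1).
#'
#' @param rmse_peaks RMSE of central-cell peak rates against
#'   [rate_model_peak()] (spikes/s).
#' @param rmse_counts RMSE of central-cell spike counts against the
#'   20-spike target.
#' @param rmse_corr RMSE of `1 - correlation` over recruited cells.
#' @return Nonnegative score (0 = perfect).
#' @export
fitness_score <- function(rmse_peaks, rmse_counts, rmse_corr) {
  1e-1 * rmse_peaks + 1e1 * rmse_counts + 1e3 * rmse_corr
}

#' Fitness of a lateral-weight candidate
#'
#' Simulates the full network at the probe amplitudes with the candidate
#' Mexican-hat scales and scores the population activity against the
#' rate-model targets: central-cell peak rates (8-ms kernel) against
#' [rate_model_peak()], central-cell spike counts against
#' `target_spikes`, and burst-profile correlations of all recruited cells
#' with the central cell (5-ms kernel) against 1. An unstable candidate
#' (spike-guard trip or a silent central cell) scores `Inf`.
#'
#' @param hat A [mexican_hat_params()] candidate.
#' @param config A [sim_config()] with the tuning table set.
#' @param amplitudes Probe amplitudes (degrees).
#' @param target_spikes Central-cell spike-count target, default 20.
#' @return List with `score` and the three component RMSEs.
#' @export
ga_fitness <- function(hat, config,
                       amplitudes = c(2, 5, 9, 14, 20, 27, 35),
                       target_spikes = 20) {
  peaks <- counts <- numeric(length(amplitudes))
  corr_dev <- list()
  for (k in seq_along(amplitudes)) {
    cfg <- config
    cfg$amplitude <- amplitudes[k]
    cfg$hat <- hat
    cfg$lateral <- TRUE
    spikes <- tryCatch(simulate_trial(cfg), error = function(e) NULL)
    if (is.null(spikes) || !length(spikes$sc[[spikes$center]]))
      return(list(score = Inf, rmse_peaks = Inf, rmse_counts = Inf,
                  rmse_corr = Inf))
    train <- spikes$sc[[spikes$center]]
    counts[k] <- length(train)
    peaks[k] <- peak_rate(spike_density(train, 8))
    corr_dev[[k]] <- 1 - population_correlations(spikes, 5)$correlation
  }
  rmse <- function(x) sqrt(mean(x^2))
  rmse_peaks <- rmse(peaks - rate_model_peak(amplitudes))
  rmse_counts <- rmse(counts - target_spikes)
  rmse_corr <- rmse(unlist(corr_dev))
  list(score = fitness_score(rmse_peaks, rmse_counts, rmse_corr),
       rmse_peaks = rmse_peaks, rmse_counts = rmse_counts,
       rmse_corr = rmse_corr)
}

# --- genetic algorithm over (w_exc, w_inh) ---------------------------------

# digit encoding: each weight as 4 decimal digits of its rounded pS value
encode_pair <- function(pair) {
  d <- function(x) {
    x <- max(0, min(9999, round(x)))
    as.integer(strsplit(sprintf("%04d", x), "")[[1]])
  }
  c(d(pair[1]), d(pair[2]))
}

decode_pair <- function(genome, bounds) {
  val <- function(d) sum(d * c(1000, 100, 10, 1))
  pmin(bounds[2], pmax(bounds[1], c(val(genome[1:4]), val(genome[5:8]))))
}

# single-point crossover on the 8-digit genome + per-digit 5% mutation
breed_pair <- function(g1, g2, mutation_prob = 0.05) {
  cut <- sample.int(7, 1)                 # crossover point 1..7
  child <- c(g1[seq_len(cut)], g2[(cut + 1):8])
  mutate <- stats::runif(8) < mutation_prob
  if (any(mutate))
    child[mutate] <- sample.int(10, sum(mutate), replace = TRUE) - 1L
  child
}

#' Genetic-algorithm search for the lateral weight scales
#'
#' Searches the `(w_exc, w_inh)` plane (pS) for the Mexican-hat scaling
#' pair minimizing [ga_fitness()], with the spatial ranges held fixed.
#' Generations of 10 candidates: the 2 best (the elites) are carried over
#' unchanged and 8 children are bred from distinct parent pairs drawn
#' from the top 6, by single-point crossover on a digit-encoded genome
#' (each weight as 4 decimal digits) with 5% per-digit mutation. The
#' search stops when the two top-ranked candidates are identical in two
#' successive generations, or at `max_generations`.
#'
#' @param config A [sim_config()] with the tuning table set.
#' @param seed RNG seed (the only source of randomness in the package).
#' @param bounds Weight bounds (pS), default `c(10, 500)`.
#' @param sigma_exc,sigma_inh Fixed Gaussian ranges (mm).
#' @param amplitudes Probe amplitudes passed to [ga_fitness()].
#' @param pop_size,n_elites,parent_pool GA shape (10 / 2 / 6 by default).
#' @param mutation_prob Per-digit mutation probability.
#' @param max_generations Hard cap on generations.
#' @return An object of class `ga_result`: `best` (a
#'   [mexican_hat_params()]), `best_fitness`, `history` (one row per
#'   candidate per generation), `converged`, and the `seed`.
#' @export
tune_lateral_weights <- function(config, seed = 1, bounds = c(10, 500),
                                 sigma_exc = 0.4, sigma_inh = 1.2,
                                 amplitudes = c(2, 5, 9, 14, 20, 27, 35),
                                 pop_size = 10, n_elites = 2,
                                 parent_pool = 6, mutation_prob = 0.05,
                                 max_generations = 50) {
  if (bounds[1] >= bounds[2]) stop("bounds must be increasing")
  set.seed(seed)
  evaluate <- function(pair) {
    hat <- mexican_hat_params(pair[1], pair[2], sigma_exc, sigma_inh)
    ga_fitness(hat, config, amplitudes)$score
  }
  pop <- lapply(seq_len(pop_size),
                function(i) stats::runif(2, bounds[1], bounds[2]))
  history <- list()
  prev_top2 <- NULL
  converged <- FALSE
  gen <- 0
  repeat {
    fitness <- vapply(pop, evaluate, numeric(1))
    ord <- order(fitness)
    pop <- pop[ord]
    fitness <- fitness[ord]
    history[[gen + 1]] <- data.frame(
      generation = gen, rank = seq_len(pop_size),
      w_exc = vapply(pop, `[`, numeric(1), 1),
      w_inh = vapply(pop, `[`, numeric(1), 2),
      fitness = fitness)
    top2 <- round(do.call(rbind, pop[1:2]))
    if (!is.null(prev_top2) && identical(top2, prev_top2)) {
      converged <- TRUE
      break
    }
    if (gen >= max_generations) break
    prev_top2 <- top2
    # breed the next generation
    genomes <- lapply(pop[seq_len(parent_pool)], encode_pair)
    pairs <- utils::combn(parent_pool, 2)
    chosen <- sample.int(ncol(pairs), pop_size - n_elites)
    children <- lapply(chosen, function(k) {
      decode_pair(breed_pair(genomes[[pairs[1, k]]],
                             genomes[[pairs[2, k]]], mutation_prob),
                  bounds)
    })
    pop <- c(pop[seq_len(n_elites)], children)
    gen <- gen + 1
  }
  best <- pop[[1]]
  structure(list(
    best = mexican_hat_params(best[1], best[2], sigma_exc, sigma_inh),
    best_fitness = fitness[1],
    history = do.call(rbind, history),
    converged = converged, generations = gen, seed = seed),
    class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Lateral-weight search (seed ", x$seed, "): ",
      if (x$converged) "converged" else "generation cap reached",
      " after ", x$generations + 1, " generation(s)\n", sep = "")
  cat("  best: w_exc =", round(x$best$w_exc), "pS, w_inh =",
      round(x$best$w_inh), "pS, fitness", format(x$best_fitness), "\n")
  invisible(x)
}
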