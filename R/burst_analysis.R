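#' Spike-density function
#'
#' Firing-rate estimate by convolution of a spike train with a unit-mass
#' Gaussian kernel: the profile is the sum of Gaussians (standard
#' deviation `kernel_width` ms) centred at the spike times, evaluated on
#' `time_grid` and expressed in spikes/s, so that its time integral equals
#' the spike count (up to kernel mass falling outside the grid).
#'
#' @param spike_times Numeric vector of spike times (ms); may be empty,
#'   which yields an all-zero profile.
#' @param kernel_width Kernel standard deviation (ms). Conventions used in
#'   the analyses: 5 ms for cross-correlations, 8 ms for peak firing
#'   rates, 3 ms for burst-shape comparisons.
#' @param time_grid Evaluation grid (ms); defaults to 0.5-ms resolution
#'   covering the spikes plus 5 kernel widths of margin.
#' @return An object of class `burst_profile` with `time` (ms) and `rate`
#'   (spikes/s).
#' @export
spike_density <- function(spike_times, kernel_width = 8, time_grid = NULL) {
  stopifnot(kernel_width > 0)
  if (is.null(time_grid)) {
    if (length(spike_times)) {
      lo <- min(spike_times) - 5 * kernel_width
      hi <- max(spike_times) + 5 * kernel_width
    } else {
      lo <- 0; hi <- 1
    }
    time_grid <- seq(lo, hi, by = 0.5)
  }
  rate <- numeric(length(time_grid))
  for (s in spike_times)
    rate <- rate + stats::dnorm(time_grid, mean = s, sd = kernel_width)
  structure(list(time = time_grid, rate = rate * 1000,  # /ms -> /s
                 n_spikes = length(spike_times),
                 kernel_width = kernel_width),
            class = "burst_profile")
}

#' @export
print.burst_profile <- function(x, ...) {
  cat("Burst profile:", x$n_spikes, "spikes, kernel", x$kernel_width,
      "ms, peak", round(peak_rate(x)), "spikes/s\n")
  invisible(x)
}

#' Peak firing rate of a burst profile
#'
#' @param profile A [spike_density()] result.
#' @return Maximum of the profile, spikes/s (0 for an empty profile).
#' @export
peak_rate <- function(profile) {
  if (!length(profile$rate)) return(0)
  max(profile$rate)
}

#' Cross-correlation of two burst profiles
#'
#' Similarity of two spike-density profiles over a window around saccade
#' onset. Both profiles are first normalized by their own peak rate, then
#' the zero-lag normalized inner product is taken over the window
#' `onset + window[1] .. onset + window[2]`:
#' `sum(Pc * Pn) / (sqrt(sum(Pc^2)) * sqrt(sum(Pn^2)))`.
#' For nonnegative profiles `r` lies in `[0, 1]`, equals 1 for profiles
#' proportional to each other, and 0 for disjoint support.
#'
#' @param p_center,p_n [spike_density()] profiles on a common time grid.
#' @param onset Saccade onset (ms): by convention the first spike of the
#'   central cell. The window is relative to it.
#' @param window Analysis window relative to onset (ms), default
#'   `c(-10, 40)`.
#' @return Correlation in `[0, 1]`.
#' @export
cross_correlation <- function(p_center, p_n, onset = 0,
                              window = c(-10, 40)) {
  if (!length(p_center$rate) || max(p_center$rate) == 0 ||
      !length(p_n$rate) || max(p_n$rate) == 0)
    stop("cross_correlation is undefined for an all-zero profile")
  if (length(p_center$time) != length(p_n$time) ||
      any(abs(p_center$time - p_n$time) > 1e-9))
    stop("profiles must share a common time grid")
  keep <- p_center$time >= onset + window[1] &
          p_center$time <= onset + window[2]
  pc <- p_center$rate[keep] / max(p_center$rate)
  pn <- p_n$rate[keep] / max(p_n$rate)
  den <- sqrt(sum(pc^2)) * sqrt(sum(pn^2))
  if (den == 0) stop("profiles have no mass inside the analysis window")
  sum(pc * pn) / den
}

#' Population cross-correlations around the central cell
#'
#' Computes the burst-profile correlation of every recruited cell with the
#' central cell of the population (cells within `radius` of the center
#' that emitted at least one spike; silent cells have no profile and are
#' excluded).
#'
#' @param spikes A [simulate_trial()] result.
#' @param kernel_width Spike-density kernel (ms), default 5.
#' @param radius Recruitment radius around the center (mm), default 0.65.
#' @param window Window around saccade onset (ms).
#' @return A data.frame with `neuron`, `distance_mm`, `correlation`
#'   (the central cell itself is excluded).
#' @export
population_correlations <- function(spikes, kernel_width = 5,
                                    radius = 0.65, window = c(-10, 40)) {
  center <- spikes$center
  members <- recruited_population(spikes$grid, spikes$config$amplitude,
                                  radius)
  if (!length(spikes$sc[[center]]))
    stop("the central cell emitted no spikes")
  onset <- spikes$sc[[center]][1]
  grid_t <- seq(onset + window[1] - 5 * kernel_width,
                onset + window[2] + 5 * kernel_width, by = 0.5)
  p_c <- spike_density(spikes$sc[[center]], kernel_width, grid_t)
  members <- setdiff(members, center)
  members <- members[lengths(spikes$sc[members]) > 0]
  corr <- vapply(members, function(nn) {
    p_n <- spike_density(spikes$sc[[nn]], kernel_width, grid_t)
    cross_correlation(p_c, p_n, onset, window)
  }, numeric(1))
  data.frame(neuron = members,
             distance_mm = abs(spikes$grid$positions[members] -
                                 spikes$grid$positions[center]),
             correlation = corr)
}

#' Movement field of a single neuron
#'
#' Spike count of a fixed SC neuron as a function of the saccade
#' amplitude: one full trial per amplitude. The count peaks at the
#' neuron's preferred (optimal) amplitude and decreases as the saccade
#' diverges from it; caudal neurons have broader fields in degrees, a
#' consequence of the exponential efferent magnification.
#'
#' @param neuron_id 1-based SC neuron index.
#' @param amplitudes Amplitudes to probe (degrees).
#' @param config A [sim_config()] with the tuning table set.
#' @return A data.frame with `amplitude` and `n_spikes`.
#' @export
movement_field <- function(neuron_id, amplitudes, config) {
  counts <- vapply(amplitudes, function(r) {
    cfg <- config
    cfg$amplitude <- r
    length(simulate_trial(cfg)$sc[[neuron_id]])
  }, numeric(1))
  data.frame(amplitude = amplitudes, n_spikes = counts)
}

#' Inter-spike intervals
#'
#' @param spike_times Numeric vector of spike times (ms).
#' @return Differences of consecutive spike times (empty for < 2 spikes).
#' @export
isi_list <- function(spike_times) {
  if (length(spike_times) < 2) return(numeric(0))
  diff(sort(spike_times))
}

#' Pooled population ISIs
#'
#' Inter-spike intervals pooled over all SC neurons of the recruited
#' population, for ISI-histogram style summaries.
#'
#' @param spikes A [simulate_trial()] result.
#' @param radius Recruitment radius (mm).
#' @return Numeric vector of ISIs (ms).
#' @export
population_isis <- function(spikes, radius = 0.65) {
  members <- recruited_population(spikes$grid, spikes$config$amplitude,
                                  radius)
  unlist(lapply(spikes$sc[members], isi_list), use.names = FALSE)
}
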