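test_that("zero input drive leaves both layers silent", {
  cfg <- cached_config()
  cfg$input <- input_params(I0 = 0)
  s <- simulate_trial(cfg)
  expect_identical(sum(spike_counts(s, "fef")), 0L)
  expect_identical(sum(spike_counts(s, "sc")), 0L)
})

test_that("identical configurations give bit-identical spike sets", {
  cfg <- cached_config()
  cfg$amplitude <- 9
  s1 <- simulate_trial(cfg)
  s2 <- simulate_trial(cfg)
  expect_identical(s1$fef, s2$fef)
  expect_identical(s1$sc, s2$sc)
})

test_that("FEF activity is translation invariant for on-grid shifts", {
  g <- build_grid()
  spacing <- g$positions[2] - g$positions[1]
  u1 <- afferent_position(15)
  k <- 20                                   # shift by 20 grid spacings
  r2 <- inverse_afferent(u1 + k * spacing)
  cfg <- cached_config()
  cfg$amplitude <- 15
  s1 <- simulate_trial(cfg)
  cfg$amplitude <- r2
  s2 <- simulate_trial(cfg)
  n <- length(g$positions)
  # the input is translation invariant only up to the residual offset
  # between u_T and the nearest grid node; align both runs on their
  # central neurons and compare the shifted spike trains
  d1 <- central_neuron(g, 15); d2 <- central_neuron(g, r2)
  expect_identical(d2 - d1, as.integer(k))
  for (i in seq_len(n - k)) {
    expect_identical(s1$fef[[i]], s2$fef[[i + k]])
  }
})

test_that("the spike-count guard aborts runaway activity with a diagnosis", {
  cfg <- cached_config()
  cfg$spike_guard <- 5L
  expect_error(simulate_trial(cfg), "runaway")
})

test_that("population spike totals are conserved across amplitudes", {
  # total spikes of the recruited population stay within 10% of their
  # mean for 5/15/25-degree targets, with and without lateral connections
  for (lat in c(TRUE, FALSE)) {
    totals <- vapply(c(5, 15, 25),
                     function(r) sum(spike_counts(cached_trial(r, lat))),
                     numeric(1))
    expect_lt(max(abs(totals - mean(totals))) / mean(totals), 0.10)
  }
})

test_that("population ISI distributions shift longer toward caudal sites", {
  med <- vapply(c(5, 15, 25),
                function(r) stats::median(population_isis(cached_trial(r))),
                numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("a simulation without a tuning table is refused", {
  expect_error(simulate_trial(sim_config()), "tuning table")
})

test_that("spike events round-trip through the plain-text format", {
  s <- cached_trial(15)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spike_events(s, path)
  expect_match(readLines(path, n = 1), "^# config [0-9a-f]{32}$")
  back <- read_spike_events(path, s$config)
  expect_equal(back$sc, s$sc)
  expect_equal(back$fef, s$fef)
  expect_identical(back$center, s$center)
})
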