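test_that("decoding is a cumulative sum of site-specific minivectors", {
  s <- cached_trial(15)
  kappa <- 2e-3
  steps <- decode_trajectory(s, kappa)
  expect_identical(nrow(steps), length(unlist(s$sc)))
  expect_true(all(diff(steps$position) > 0))   # all minivectors rostral-positive
  # endpoint equals the weighted spike sum regardless of timing
  counts <- lengths(s$sc)
  endpoint <- kappa * sum(counts * inverse_afferent(s$grid$positions))
  expect_equal(steps$position[nrow(steps)], endpoint, tolerance = 1e-9)
  # a silent population decodes to an empty trace
  s0 <- s
  s0$sc <- lapply(s0$sc, function(x) numeric(0))
  expect_identical(nrow(decode_trajectory(s0, kappa)), 0L)
})

test_that("kappa calibration puts the 21-degree endpoint exactly on target", {
  cfg <- cached_config()
  cal <- calibrate_kappa(cfg)
  e <- eye_trace(cal$spikes, cal$kappa)
  expect_equal(e$endpoint, 21, tolerance = 1e-9)
  # calibration is inverse-linear in the weighted spike sum
  expect_equal(calibrate_kappa(cfg)$kappa, cal$kappa)
  expect_gt(cal$kappa, 0)
})

test_that("smoothing-differentiation preserves ramps and integrates back", {
  # build a synthetic spike set whose decoded positions form a ramp
  s <- cached_trial(15)
  ramp <- s
  ramp$sc <- lapply(seq_along(ramp$sc), function(i) numeric(0))
  ramp$sc[[central_neuron(s$grid, 15)]] <- seq(50, 150, by = 1)
  kappa <- 1e-3
  e <- eye_trace(ramp, kappa, sg_window = 15)
  step_deg <- kappa * inverse_afferent(
    s$grid$positions[central_neuron(s$grid, 15)])
  # interior of the ramp: constant velocity equal to the slope
  mid <- e$time > 70 & e$time < 130
  expect_equal(e$velocity[mid], rep(step_deg * 1000, sum(mid)),
               tolerance = 1e-6)
  # velocity integrates back to the endpoint
  expect_equal(sum(e$velocity) * 1e-3, e$endpoint, tolerance = 0.02)
  # a real trace integrates back too
  er <- eye_trace(s, cached_kappa())
  expect_equal(sum(er$velocity) * 1e-3, er$endpoint, tolerance = 0.02)
})

test_that("decoded endpoints land near their targets across the map", {
  kappa <- cached_kappa()
  for (r in c(5, 15, 25)) {
    e <- eye_trace(cached_trial(r), kappa)
    expect_lt(abs(e$endpoint - r) / r, 0.15)
  }
})

test_that("peak eye velocity grows with saccade amplitude", {
  kappa <- cached_kappa()
  pk <- vapply(c(5, 15, 25),
               function(r) eye_trace(cached_trial(r), kappa)$peak_velocity,
               numeric(1))
  expect_true(all(diff(pk) > 0))
})

test_that("the peak-velocity ratio reflects the lateral-interaction regime", {
  cfg <- cached_config()
  # zero-weight hat: the two conditions are identical simulations
  pr0 <- peak_velocity_ratio(mexican_hat_params(0, 0), cfg)
  expect_equal(pr0$ratio, 1, tolerance = 1e-9)
  # the balanced default hat accelerates the eye
  pr <- peak_velocity_ratio(mexican_hat_params(), cfg)
  expect_gt(pr$ratio, 1)
  # overwhelming inhibition stretches the bursts below baseline speed
  pr300 <- peak_velocity_ratio(mexican_hat_params(w_inh = 300), cfg)
  expect_lt(pr300$ratio, 1)
})
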