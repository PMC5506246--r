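test_that("rest is near-equilibrium and reset follows the spike rule", {
  p <- adex_params("SC")
  s <- adex_step(list(V = p$E_L, q = 0), 0, p, dt = 1)
  # residual drift is only the tiny exponential tail at rest
  expect_lt(abs(s$V - p$E_L), 1e-4)
  expect_false(s$spiked)
  # a state driven past V_peak resets to V_r and increments q by b
  V0 <- p$V_peak - 0.01
  s2 <- adex_step(list(V = V0, q = 0), 5000, p, dt = 0.01)
  expect_true(s2$spiked)
  expect_identical(s2$V, p$V_r)
  # pre-reset Euler update of q, then the spike-triggered jump b
  expect_equal(s2$q, 0.01 / p$tau_q * p$a * (V0 - p$E_L) + p$b,
               tolerance = 1e-9)
  expect_error(adex_step(list(V = NaN, q = 0), 0, p, 0.01), "finite")
})

test_that("compiled integrator agrees with the R reference step", {
  p <- adex_params("FEF")
  dt <- 0.01
  n_steps <- 5000
  t <- (seq_len(n_steps) - 1) * dt
  I <- external_current(0, 0, t)
  out <- integrate_neuron(p, dt, n_steps * dt, I_ext = I, traces = TRUE)
  st <- list(V = p$E_L, q = 0)
  spikes_r <- numeric(0)
  for (k in seq_len(n_steps)) {
    st <- adex_step(st, I[k], p, dt)
    if (st$spiked) spikes_r <- c(spikes_r, k * dt)
  }
  expect_equal(out$spikes, spikes_r, tolerance = 1e-12)
  expect_equal(out$V[n_steps + 1], st$V, tolerance = 1e-9)
  expect_equal(out$q[n_steps + 1], st$q, tolerance = 1e-9)
})

test_that("subthreshold dynamics match the analytic linear solution", {
  # exponential term pushed far away: the system is linear in (V, q)
  p <- adex_params("SC", V_T = 500, V_peak = 600)
  I <- 100  # pA, subthreshold
  out <- integrate_neuron(p, dt = 0.01, horizon = 100,
                          I_ext = rep(I, 10000), traces = TRUE)
  A <- matrix(c(-p$g_L / p$C, -1 / p$C,
                p$a / p$tau_q, -1 / p$tau_q), 2, 2, byrow = TRUE)
  b <- c(I / p$C, 0)
  xstar <- solve(-A, b)                     # fixed point of (V - E_L, q)
  ex <- Matrix::expm(A * 100)
  x100 <- as.numeric(ex %*% (c(0, 0) - xstar)) + xstar
  expect_length(out$spikes, 0)
  expect_equal(out$V[10001] - p$E_L, x100[1], tolerance = 1e-3)
  expect_equal(out$q[10001], x100[2], tolerance = 1e-3)
})

test_that("the Euler solution converges first-order under dt refinement", {
  # smooth current drive: spike count is dt-stable and the spike-time
  # error contracts linearly with the step (late spikes accumulate phase
  # drift, so the error is measured by its contraction, not its size)
  train_at <- function(dt) {
    n <- round(300 / dt)
    t <- (seq_len(n) - 1) * dt
    integrate_neuron(adex_params("FEF"), dt, 300,
                     I_ext = external_current(0, 0, t))$spikes
  }
  s_coarse <- train_at(0.02)
  s_mid <- train_at(0.01)
  s_fine <- train_at(0.005)
  expect_length(s_mid, length(s_coarse))
  expect_length(s_fine, length(s_coarse))
  err_coarse <- max(abs(s_coarse - s_mid))
  err_mid <- max(abs(s_mid - s_fine))
  expect_gt(err_coarse / err_mid, 1.5)
  # the first spike is step-insensitive
  expect_lt(abs(s_mid[1] - s_fine[1]), 0.05)
})

test_that("tuned SC bursts keep their core under time-step refinement", {
  ref <- cached_ref_train()
  for (tau in c(20, 60)) {
    p <- adex_params("SC", tau_q = tau)
    w <- predict(cached_fit(), tau)
    s1 <- integrate_neuron(p, dt = 0.01, horizon = 300,
                           pre_spikes = ref, w = w)$spikes
    s2 <- integrate_neuron(p, dt = 0.005, horizon = 300,
                           pre_spikes = ref, w = w)$spikes
    # counts may flip by one marginal tail spike, never more
    expect_lte(abs(length(s1) - length(s2)), 1)
    expect_lt(max(abs(s1[1:10] - s2[1:10])), 0.3)
  }
})

test_that("SC bursts terminate through monotone adaptation build-up", {
  # V_r > V_T: after each reset the exponential term re-drives the cell,
  # so only the accumulating adaptation current can stop the burst
  p <- adex_params("SC", tau_q = 40)
  expect_gt(p$V_r, p$V_T)
  out <- integrate_neuron(p, dt = 0.01, horizon = 300,
                          pre_spikes = cached_ref_train(),
                          w = predict(cached_fit(), 40), traces = TRUE)
  expect_gt(length(out$spikes), 5)
  q_at_spikes <- out$q[round(out$spikes / 0.01) + 1]
  expect_true(all(diff(q_at_spikes) > 0))
})

test_that("an unstimulated neuron stays silent", {
  out <- integrate_neuron(adex_params("SC"), dt = 0.01, horizon = 100)
  expect_length(out$spikes, 0)
})
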