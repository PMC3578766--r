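test_that("parameter constructors enforce their invariants", {
  expect_error(neuron_params(v_thresh = -70), "exceed")
  expect_error(network_params(w_ie_max = 5, w_ii_max = 6), "equal")
  expect_error(weight_matrix(matrix(1, 3, 3), 2), "diagonal")
  W <- matrix(3, 3, 3); diag(W) <- 0
  expect_error(weight_matrix(W, 2), "0, w_max")
})

test_that("subthreshold bias produces no spikes; suprathreshold ISI matches the closed form", {
  np <- neuron_params() # tau_m 20, 10 mV gap
  p <- isolated_params(mu = 8, sigma = 0)
  s <- simulate_network(p, np, initial_weights = zero_weights(3),
                        duration_s = 1, plasticity = FALSE)
  expect_equal(nrow(s$raster$events), 0)

  # mu above the gap: ISI = tau_m log(mu / (mu - gap)), here 20 log(6)
  p2 <- isolated_params(n_exc = 1, n_inh = 1, mu = 12, sigma = 0)
  s2 <- simulate_network(p2, np, initial_weights = zero_weights(1),
                         duration_s = 5, plasticity = FALSE)
  tt <- s2$raster$events$time_ms[s2$raster$events$neuron == 1]
  expect_gt(length(tt), 100)
  isi <- mean(diff(tt))
  expect_lt(abs(isi - 20 * log(6)) / (20 * log(6)), 0.005)
})

test_that("plasticity off returns the initial weights bit-exactly and seeds are reproducible", {
  np <- neuron_params()
  p <- network_params(n_exc = 8, n_inh = 4, seed = 2)
  W0 <- random_weight_matrix(8, p$w_max_ee, seed = 3)
  s <- simulate_network(p, np, initial_weights = W0, duration_s = 1,
                        plasticity = FALSE, seed = 5)
  expect_identical(unclass(s$weights), unclass(W0))
  s2 <- simulate_network(p, np, initial_weights = W0, duration_s = 1,
                         plasticity = FALSE, seed = 5)
  expect_identical(s$raster$events, s2$raster$events)
  s3 <- simulate_network(p, np, initial_weights = W0, duration_s = 1,
                         plasticity = FALSE, seed = 6)
  expect_false(identical(s$raster$events, s3$raster$events))
})

test_that("without noise the spike count is invariant across repeated runs", {
  np <- neuron_params()
  # isolated fixed blocks so the dynamics depend only on the E-to-E
  # weights, which are held identical across the two runs
  p <- isolated_params(n_exc = 6, n_inh = 3, mu = 14, sigma = 0)
  W0 <- random_weight_matrix(6, p$w_max_ee, seed = 1)
  n1 <- nrow(simulate_network(p, np, initial_weights = W0, duration_s = 1,
                              plasticity = FALSE, seed = 1)$raster$events)
  n2 <- nrow(simulate_network(p, np, initial_weights = W0, duration_s = 1,
                              plasticity = FALSE, seed = 99)$raster$events)
  expect_identical(n1, n2)
})

test_that("plastic weights respect the hard bounds at every recorded point", {
  np <- neuron_params()
  for (seed in 1:2) {
    win <- stdp_window(0.05, 0.05, 20, 20, 0, "all_to_all", 0.4)
    p <- network_params(n_exc = 20, n_inh = 10, w_max_ee = 0.4, mu = 90,
                        seed = seed)
    s <- simulate_network(p, np, win, duration_s = 5, plasticity = TRUE,
                          seed = seed)
    expect_gte(min(s$weights), 0)
    expect_lte(max(s$weights), 0.4)
    expect_true(all(diag(unclass(s$weights)) == 0))
  }
})

test_that("online STDP equals offline replay of the recorded raster", {
  np <- neuron_params()
  # all-to-all, unshifted
  p <- network_params(n_exc = 5, n_inh = 3, w_max_ee = 0.6, mu = 95, seed = 4)
  win <- stdp_window(0.03, 0.025, 18, 22, 0, "all_to_all", 0.6)
  W0 <- random_weight_matrix(5, 0.6, seed = 8)
  s <- simulate_network(p, np, win, initial_weights = W0, duration_s = 3,
                        plasticity = TRUE, seed = 4)
  expect_gt(nrow(s$raster$events), 50)
  W_rep <- replay_stdp(s$raster, win, W0)
  expect_equal(unclass(s$weights), unclass(W_rep), tolerance = 1e-8)

  # nearest-neighbor, shifted window
  win2 <- stdp_window(0.03, 0.02, 15, 15, 4, "nearest_neighbor", 0.6)
  s2 <- simulate_network(p, np, win2, initial_weights = W0, duration_s = 3,
                         plasticity = TRUE, seed = 4)
  W_rep2 <- replay_stdp(s2$raster, win2, W0)
  expect_equal(unclass(s2$weights), unclass(W_rep2), tolerance = 1e-8)
})

test_that("bias calibration hits the target rate and is monotone", {
  np <- neuron_params()
  p <- scale_network(0.1, seed = 1) # 50 E + 25 I
  mu <- calibrate_bias(p, np, 15, tolerance = 1.5, seed = 1, probe_s = 4)
  expect_lt(abs(attr(mu, "rate_hz") - 15), 1.5)
  mu_hi <- calibrate_bias(p, np, 30, tolerance = 1.5, seed = 1, probe_s = 4)
  expect_gt(as.numeric(mu_hi), as.numeric(mu))
  expect_error(calibrate_bias(p, np, 0), "positive")
  expect_error(calibrate_bias(p, np, 20, tolerance = 1, seed = 1,
                              probe_s = 4, mu_range = c(0, 1)),
               "calibration failure")
})

test_that("steady-state detection accepts constant series and rejects drifting ones", {
  t <- seq(2, 100, by = 2)
  const <- data.frame(time_s = t, rate_hz = 20, w_mean = 0.4, w_var = 0.01)
  ss <- detect_steady_state(const, window_s = 20, slope_tol = 0.05)
  expect_true(ss$converged)
  expect_equal(ss$time_s, 20) # first time a full window is available

  drift <- const
  drift$w_mean <- seq(0.1, 0.8, length.out = length(t))
  ss2 <- detect_steady_state(drift, window_s = 20, slope_tol = 0.05)
  expect_false(ss2$converged)

  expect_error(detect_steady_state(const[1:5, ], window_s = 50), "window")
})
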