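test_that("regime definitions satisfy their window invariants", {
  rb <- regime_spec("balanced")
  expect_equal(rb$window$a_plus * rb$window$tau_plus,
               rb$window$a_minus * rb$window$tau_minus)
  expect_equal(rb$window$shift, 0)

  rp <- regime_spec("potentiation_dominant")
  expect_gt(rp$window$a_plus * rp$window$tau_plus,
            rp$window$a_minus * rp$window$tau_minus)

  rd <- regime_spec("depression_dominant")
  expect_gt(rd$window$a_minus * rd$window$tau_minus,
            rd$window$a_plus * rd$window$tau_plus)

  rr <- regime_spec("rightward_shifted")
  expect_gt(rr$window$shift, 0)
  expect_equal(rr$window$pairing, "nearest_neighbor")
  expect_gt(rr$window$a_plus * rr$window$tau_plus,
            rr$window$a_minus * rr$window$tau_minus)

  rl <- regime_spec("leftward_shifted")
  expect_lt(rl$window$shift, 0)
  expect_gt(rl$window$a_minus * rl$window$tau_minus,
            rl$window$a_plus * rl$window$tau_plus)
  # mirrored parameter sets
  expect_equal(rl$window$a_plus, rr$window$a_minus)
  expect_equal(rl$window$a_minus, rr$window$a_plus)
  expect_equal(rl$window$shift, -rr$window$shift)
})

test_that("network scaling preserves the total synaptic drive", {
  base <- network_params()
  p <- scale_network(0.4, base)
  expect_equal(p$n_exc * p$w_max_ee, base$n_exc * base$w_max_ee)
  expect_equal(p$n_inh * p$w_ie_max, base$n_inh * base$w_ie_max)
  w <- scale_window(regime_spec("balanced")$window, 0.4)
  expect_equal(w$a_plus, regime_spec("balanced")$window$a_plus / 0.4)
  expect_equal(w$w_max, p$w_max_ee)
  expect_error(scale_network(0), "scale")
})

test_that("Poisson raster generator hits the requested rates deterministically", {
  expect_equal(nrow(make_poisson_raster(0, 10, seed = 1)$events), 0)
  r <- make_poisson_raster(rep(20, 5), duration_s = 100, seed = 2)
  emp <- vapply(1:5, function(i)
    sum(r$events$neuron == i) / 100, numeric(1))
  expect_true(all(abs(emp - 20) < 3 * sqrt(20 / 100)))
  expect_identical(make_poisson_raster(c(5, 10), 5, seed = 9)$events,
                   make_poisson_raster(c(5, 10), 5, seed = 9)$events)
  expect_false(identical(make_poisson_raster(c(5, 10), 5, seed = 9)$events,
                         make_poisson_raster(c(5, 10), 5, seed = 10)$events))
  expect_error(make_poisson_raster(-1, 5), ">= 0")
})

test_that("planted graphs carry their ground-truth loop counts", {
  g <- make_planted_graph(6, planted = 3)
  expect_equal(count_loops(binarize(g$weights, g$theta), 3), 3)
  expect_equal(g$cycles[[1]], 1:3)

  g2 <- make_planted_graph(10, planted = c(2, 2))
  expect_equal(count_loops(binarize(g2$weights, g2$theta), 2), 4)

  g3 <- make_planted_graph(10, planted = c(2, 2), background = 0.1, seed = 3)
  A0 <- binarize(g2$weights, 0.5); A1 <- binarize(g3$weights, 0.5)
  expect_true(all(count_loops(A1, 2:5) >= count_loops(A0, 2:5)))

  expect_error(make_planted_graph(4, planted = c(3, 3)), "fit")
  expect_error(make_planted_graph(5, planted = 1), ">= 2")
})

test_that("a micro regime run produces a complete report", {
  spec <- regime_spec("balanced")
  rep1 <- run_regime(spec, initial_rates = 15, scale = 0.08, seeds = 1,
                     max_duration_s = 40, chunk_s = 20, ss_window_s = 16,
                     n_shuffles = 3)
  res <- rep1$results
  expect_equal(nrow(res), 1)
  expect_true(is.finite(res$steady_rate))
  expect_true(is.finite(res$w_mean_frac))
  expect_true(is.finite(res$recurrence_index))
  key <- names(rep1$reports)[1]
  expect_s3_class(rep1$reports[[key]]$loops, "loop_report")
  expect_s3_class(rep1$reports[[key]]$hubs, "hub_report")
})
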