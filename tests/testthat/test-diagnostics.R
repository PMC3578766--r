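test_that("independent Poisson trains have near-zero average cross-covariance", {
  r <- make_poisson_raster(rep(20, 12), duration_s = 60, seed = 3)
  cc <- cross_covariance(r, n_pairs = 60, bin_ms = 1, max_lag_ms = 50, seed = 1)
  # variance scale of a 20 Hz train in 1 ms bins is ~0.02; the pair
  # average should sit well below it at every lag
  expect_lt(max(abs(cc$curve$avg_cov)), 0.004)
  expect_equal(cc$n_pairs, 60)
})

test_that("a time-shifted copy of a train shows a cross-covariance peak at the shift", {
  tt <- sort(with_local_seed(4, runif(1500, 0, 30000)))
  shift <- 10
  ev_t <- c(tt, tt + shift)
  ev_n <- rep(1:2, each = length(tt))
  o <- order(ev_t)
  r <- spike_raster(ev_t[o], ev_n[o], 0, 30000 + shift, n_exc = 2)
  cc <- cross_covariance(r, n_pairs = 2, bin_ms = 1, max_lag_ms = 40, seed = 1)
  peak <- cc$curve$lag_ms[which.max(cc$curve$avg_cov)]
  expect_equal(abs(peak), shift, tolerance = 1)
})

test_that("ISI CV is near 1 for Poisson trains and 0 for periodic ones", {
  rp <- make_poisson_raster(rep(20, 20), duration_s = 100, seed = 6)
  cv <- isi_cv(rp, n_sample = 20, seed = 1)
  expect_lt(abs(as.numeric(cv) - 1), 0.12)

  per <- seq(10, 50000, by = 40)
  rper <- spike_raster(per, rep(1L, length(per)), 0, 50000, n_exc = 1)
  expect_equal(as.numeric(isi_cv(rper, 1, seed = 1)), 0)

  # neurons with too few spikes are skipped and counted
  sparse <- spike_raster(c(1, 2, 100, 200, 300), c(1L, 1L, 2L, 2L, 2L),
                         0, 1000, n_exc = 2)
  cv2 <- isi_cv(sparse, 2, seed = 1)
  expect_equal(attr(cv2, "n_skipped"), 1L)
  none <- spike_raster(c(1, 2), c(1L, 2L), 0, 100, n_exc = 2)
  expect_error(isi_cv(none, 2), ">= 3 spikes")
})

test_that("cross-covariance rejects undersized samples", {
  r <- make_poisson_raster(rep(20, 3), duration_s = 10, seed = 1)
  expect_error(cross_covariance(r, n_pairs = 500, seed = 1), "fewer")
})
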