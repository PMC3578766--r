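test_that("rasters round-trip through CSV", {
  r <- make_poisson_raster(c(10, 30), duration_s = 5, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_raster(r, path)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, "time_ms,neuron_id")
  r2 <- read_raster(path, n_exc = 2, t_start_ms = 0, t_end_ms = 5000)
  expect_equal(r2$events$time_ms, r$events$time_ms)
  expect_equal(r2$events$neuron, r$events$neuron)
})

test_that("weight matrices round-trip through CSV with a JSON sidecar", {
  W <- random_weight_matrix(6, 0.8, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_weights(W, path)
  expect_true(file.exists(paste0(path, ".json")))
  W2 <- read_weights(path)
  expect_equal(unclass(W2), unclass(W), tolerance = 1e-12)
  expect_equal(attr(W2, "w_max"), 0.8)
})

test_that("loop and hub reports serialize to JSON with raw counts retained", {
  W <- random_weight_matrix(12, 1, seed = 6)
  lr <- loop_ratio_report(W, "mean", lengths = 2:4, n_shuffles = 3, seed = 1)
  obj <- jsonlite::fromJSON(report_to_json(lr))
  expect_equal(obj$kind, "loop_report")
  expect_equal(obj$census$n_real, lr$census$n_real)
  hr <- hub_report(W, "mean")
  obj2 <- jsonlite::fromJSON(report_to_json(hr))
  expect_equal(obj2$degrees$in_deg, hr$degrees$in_deg)
  expect_error(report_to_json(list()), "unsupported")
})
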