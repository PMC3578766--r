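test_that("window construction enforces the parameter invariants", {
  expect_s3_class(stdp_window(0.01, 0.01), "stdp_window")
  expect_error(stdp_window(-0.01, 0.01), "a_plus")
  expect_error(stdp_window(0.01, 0.01, tau_plus = 0), "tau_plus")
  expect_error(stdp_window(0.01, 0.01, w_max = 0), "w_max")
  expect_error(stdp_window(0.01, 0.01, shift = 2, pairing = "all_to_all"),
               "nearest_neighbor")
  expect_s3_class(stdp_window(0.01, 0.01, shift = -3,
                              pairing = "nearest_neighbor"), "stdp_window")
})

test_that("window value follows the two-branch exponential with the shift", {
  w <- stdp_window(0.02, 0.015, 18, 22, shift = 0, w_max = 1)
  expect_equal(window_value(5, w), 0.02 * exp(-5 / 18))
  expect_equal(window_value(-7, w), -0.015 * exp(-7 / 22))
  # decay to zero far from the origin
  expect_lt(abs(window_value(500, w)), 1e-10)
  expect_lt(abs(window_value(-500, w)), 1e-10)
  # unshifted window: simultaneous spikes contribute nothing
  expect_identical(window_value(0, w), 0)
  expect_error(window_value(NaN, w), "finite")

  # odd symmetry of the balanced window
  wb <- stdp_window(0.01, 0.01, 20, 20)
  s <- c(0.1, 1, 5, 17, 60)
  expect_equal(window_value(s, wb), -window_value(-s, wb))

  # rightward shift: pre-before-post at short intervals depresses
  wr <- stdp_window(0.01, 0.008, 20, 20, shift = 4,
                    pairing = "nearest_neighbor")
  expect_lt(window_value(2, wr), 0)
  # the boundary dt == shift belongs to the potentiation branch
  expect_equal(window_value(4, wr), 0.01)
})

test_that("window integral matches the closed form A+tau+ - A-tau-", {
  for (pars in list(c(0.012, 0.01, 17, 23), c(0.01, 0.01, 20, 20),
                    c(0.005, 0.02, 35, 12))) {
    w <- stdp_window(pars[1], pars[2], pars[3], pars[4])
    s <- seq(-2000, 2000, by = 0.01)
    num <- sum(window_value(s, w)) * 0.01
    expect_equal(num, pars[1] * pars[3] - pars[2] * pars[4], tolerance = 5e-3)
  }
})

test_that("window sign equals sign(dt - shift) away from the boundary", {
  cases <- expand.grid(shift = c(-6, 0, 3, 11), seed = 1:3)
  for (i in seq_len(nrow(cases))) {
    d <- cases$shift[i]
    w <- stdp_window(0.01, 0.012, 15, 25, shift = d,
                     pairing = "nearest_neighbor")
    dt <- with_local_seed(cases$seed[i], runif(200, -100, 100))
    dt <- dt[abs(dt - d) > 1e-6 & dt != 0]
    expect_equal(sign(window_value(dt, w)), sign(dt - d))
  }
})

test_that("all-to-all pairing returns the full Cartesian interval set", {
  p <- pair_spikes(10, 15, "all_to_all")
  expect_equal(p$dt, 5)
  p2 <- pair_spikes(c(10, 20), 15, "all_to_all")
  expect_setequal(p2$dt, c(5, -5))
  expect_equal(nrow(pair_spikes(1:7 * 3, 2:5 * 7, "all_to_all")), 28)
  expect_equal(nrow(pair_spikes(numeric(0), 1:3, "all_to_all")), 0)
  expect_error(pair_spikes(c(5, 2), 1, "all_to_all"), "ascending")
})

test_that("nearest-neighbor pairing matches an exhaustive rule oracle", {
  # oracle: plain double loops over the reduced symmetric rule
  nn_oracle <- function(pre, post) {
    ev <- list()
    for (j in seq_along(post)) {
      cand <- which(pre <= post[j])
      if (length(cand)) ev[[length(ev) + 1]] <-
          c(pre = max(cand), post = j)
    }
    for (i in seq_along(pre)) {
      cand <- which(post <= pre[i])
      if (length(cand)) ev[[length(ev) + 1]] <-
          c(pre = i, post = max(cand))
    }
    ev <- unique(do.call(rbind, ev))
    ev <- ev[order(ev[, "post"], ev[, "pre"]), , drop = FALSE]
    data.frame(dt = post[ev[, "post"]] - pre[ev[, "pre"]],
               pre_index = as.integer(ev[, "pre"]),
               post_index = as.integer(ev[, "post"]))
  }
  expect_equal(pair_spikes(c(10, 20), 15, "nearest_neighbor"),
               nn_oracle(c(10, 20), 15))
  for (seed in 1:8) {
    pre <- sort(with_local_seed(seed, runif(12, 0, 200)))
    post <- sort(with_local_seed(seed + 100, runif(9, 0, 200)))
    got <- pair_spikes(pre, post, "nearest_neighbor")
    expect_equal(got, nn_oracle(pre, post), tolerance = 1e-12)
    expect_lte(nrow(got), length(pre) + length(post))
  }
  # exact ties are counted once
  tie <- pair_spikes(c(5, 9), c(9, 12), "nearest_neighbor")
  expect_equal(sum(tie$dt == 0), 1)
})

test_that("hard bounds clip and never leave [0, w_max]", {
  w <- stdp_window(0.01, 0.01, w_max = 1)
  expect_equal(apply_hard_bounds(0.9, 0.3, w), 1)
  expect_equal(apply_hard_bounds(0.1, -0.5, w), 0)
  expect_equal(apply_hard_bounds(0.5, 0, w), 0.5)
  expect_error(apply_hard_bounds(1.2, 0, w), "outside")
  ws <- with_local_seed(5, runif(500, 0, 1))
  ds <- with_local_seed(6, runif(500, -3, 3))
  out <- apply_hard_bounds(ws, ds, w)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("window serializes to flat JSON and back", {
  w <- stdp_window(0.011, 0.009, 19, 21, shift = 2.5,
                   pairing = "nearest_neighbor", w_max = 0.7)
  path <- tempfile(fileext = ".json")
  window_to_json(w, path)
  w2 <- window_from_json(path)
  expect_equal(w2, w)
  keys <- names(jsonlite::fromJSON(path))
  expect_setequal(keys, c("a_plus", "a_minus", "tau_plus", "tau_minus",
                          "shift_ms", "pairing", "w_max"))
})
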