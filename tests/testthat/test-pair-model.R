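# Synthetic drift coefficients for phase-plane tests that need no
# simulation: a list with the same fields fixed_points() and
# phase_portrait() consume.
synth_coeffs <- function(alpha, beta, gamma) {
  structure(list(alpha = rep(alpha, 2), beta = rep(beta, 2),
                 gamma = rep(gamma, 2), r = c(20, 20),
                 pairing = "all_to_all"), class = "drift_coefficients")
}

test_that("pair configuration validates its inputs", {
  w <- stdp_window(0.01, 0.01)
  expect_error(pair_config(-1, 10, w), ">= 0")
  expect_s3_class(pair_config(0, 0, w), "pair_config")
})

test_that("the PSP kernel is causal with unit-weight integral tau_s", {
  s <- seq(0, 600, by = 0.01)
  expect_equal(sum(psp_kernel(s, 20, 5)) * 0.01, 5, tolerance = 1e-3)
  expect_equal(psp_kernel(c(-3, 0), 20, 5), c(0, 0))
  expect_true(all(psp_kernel(s[-1], 20, 5) > 0))
})

test_that("fixed points solve the linear system and classify by eigenvalues", {
  # potentiation-dominated pattern: both coordinates negative, unstable
  co <- synth_coeffs(alpha = 0.0021, beta = 0.002, gamma = 0.004)
  fp <- fixed_points(co, w_max = 1)
  expect_equal(fp$type, "unstable_node")
  expect_equal(fp$location, rep(0.004 / (0.002 - 0.0021), 2))
  expect_true(all(fp$location < 0))
  expect_false(fp$inside)

  # depression-dominated: saddle below the origin
  fp2 <- fixed_points(synth_coeffs(0.002, 0.0021, -0.004), w_max = 1)
  expect_equal(fp2$type, "saddle")
  expect_true(all(fp2$location < 0))

  # homeostatic pattern: stable node inside the square
  fp3 <- fixed_points(synth_coeffs(-0.004, 0.002, 0.001), w_max = 1)
  expect_equal(fp3$type, "stable_node")
  expect_equal(fp3$location, rep(0.001 / 0.006, 2))
  expect_true(fp3$inside && fp3$positive)

  # balanced: line of equilibria along the diagonal, transversally unstable
  fpl <- fixed_points(synth_coeffs(0.002, 0.002, 0), w_max = 1)
  expect_equal(fpl$type, "line")
  expect_equal(fpl$line$slope, 1)
  expect_false(fpl$transverse_stable)

  # singular with nonzero baseline drift: no fixed point
  expect_equal(fixed_points(synth_coeffs(0.002, 0.002, 0.001), 1)$type, "none")
  expect_error(fixed_points(synth_coeffs(NA, 1, 0), 1), "finite")
})

test_that("symmetric-rate Jacobian has (1,1)/(1,-1) eigenstructure", {
  for (ab in list(c(0.003, 0.001), c(0.001, 0.004), c(-0.002, 0.001))) {
    co <- synth_coeffs(ab[1], ab[2], 0.0005)
    fp <- fixed_points(co, 1)
    expect_setequal(round(fp$eigenvalues, 12),
                    round(c(ab[1] - ab[2], ab[1] + ab[2]), 12))
    M <- rbind(c(ab[1], -ab[2]), c(-ab[2], ab[1]))
    expect_equal(drop(M %*% c(1, 1)), (ab[1] - ab[2]) * c(1, 1))
    expect_equal(drop(M %*% c(1, -1)), (ab[1] + ab[2]) * c(1, -1))
  }
})

test_that("phase portraits recover the regime basin structures", {
  # balanced: diagonal equilibria, off-diagonal cells split between the
  # two unidirectional corner attractors
  ppb <- phase_portrait(synth_coeffs(0.002, 0.002, 0), w_max = 1, grid_n = 11)
  labs <- ppb$attractors$attractor
  expect_true(all(c("uni_1to2", "uni_2to1") %in% labs))
  expect_equal(basin_fraction(ppb, "uni_1to2"),
               basin_fraction(ppb, "uni_2to1"))
  diag_cells <- ppb$grid[abs(ppb$grid$w12 - ppb$grid$w21) < 1e-9, ]
  expect_true(all(diag_cells$attractor == "equilibrium_line"))
  off <- ppb$grid[ppb$grid$w12 > ppb$grid$w21, ]
  expect_true(all(off$attractor == "uni_1to2"))

  # potentiation-dominated: three basins including the recurrent corner
  ppp <- phase_portrait(synth_coeffs(0.0021, 0.002, 0.0006), 1, grid_n = 11)
  expect_setequal(ppp$attractors$attractor,
                  c("recurrent", "uni_1to2", "uni_2to1"))

  # depression-dominated: origin plus the two unidirectional corners
  ppd <- phase_portrait(synth_coeffs(0.002, 0.0021, -0.0006), 1, grid_n = 11)
  expect_setequal(ppd$attractors$attractor,
                  c("origin", "uni_1to2", "uni_2to1"))

  # interior stable fixed point absorbs everything
  ppi <- phase_portrait(synth_coeffs(-0.004, 0.002, 0.002), 1, grid_n = 9)
  expect_equal(basin_fraction(ppi, "interior"), 1)
  expect_error(basin_fraction(ppi, "recurrent"), "not present")

  for (pp in list(ppb, ppp, ppd, ppi)) {
    expect_equal(sum(pp$attractors$fraction), 1)
    expect_equal(pp$n_unresolved, 0)
  }
})

test_that("basin labels are stable under integration-step refinement", {
  co <- synth_coeffs(0.0021, 0.002, 0.0006)
  p1 <- phase_portrait(co, 1, grid_n = 9)
  p2 <- phase_portrait(co, 1, grid_n = 9, max_steps = 240000)
  expect_identical(p1$grid$attractor, p2$grid$attractor)
  expect_error(phase_portrait(co, 1, grid_n = 2), "grid_n")
})

test_that("balanced drift coefficients vanish at baseline and are symmetric", {
  w <- stdp_window(0.04, 0.04, 20, 20, 0, "all_to_all", 0.8)
  cfg <- pair_config(20, 20, w)
  co <- drift_coefficients(cfg)
  expect_equal(unname(co$gamma), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(co$alpha), unname(co$beta))
  expect_gt(co$alpha[1], 0)
  # zero weights, zero rates: drift is trivially zero
  z <- simulate_pair(pair_config(0, 0, w), 0, 0)
  expect_equal(z$drift, c(0, 0))
  expect_error(simulate_pair(pair_config(0, 0, w), 0.2, 0), "zero baseline")
  expect_error(simulate_pair(cfg, 2, 0), "w_max")
})

test_that("rate scans report the maximal stable-positive interval", {
  w <- stdp_window(0.04, 0.04, 20, 20, 0, "all_to_all", 0.8)
  expect_error(rate_scan(w, c(20, 10)), "ascending")
  # depression-dominated unshifted window: never a stable positive point
  wd <- regime_spec("depression_dominant")$window
  rs <- rate_scan(wd, c(10, 20, 30))
  expect_null(rs$stable_interval)
  expect_true(all(rs$scan$type == "saddle"))
})
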