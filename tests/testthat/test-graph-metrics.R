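test_that("binarize applies the >= threshold and zeroes the diagonal", {
  W <- matrix(0.5, 4, 4); diag(W) <- 0
  A <- binarize(W, "mean")
  expect_true(all(A[row(A) != col(A)] == 1L)) # w >= w under the mean rule
  expect_true(all(diag(A) == 0L))
  expect_equal(attr(A, "theta"), 0.5)

  expect_true(all(binarize(W, 0.9) == 0L))

  W3 <- rbind(c(0, 0.2, 0.9), c(0.6, 0, 0.1), c(0.4, 0.8, 0))
  A3 <- binarize(W3, "mean") # mean of off-diagonal = 0.5
  expect_equal(unclass(A3),
               rbind(c(0L, 0L, 1L), c(1L, 0L, 0L), c(0L, 1L, 0L)),
               ignore_attr = TRUE)
  expect_error(binarize(W3, -1), ">= 0")
})

test_that("count_loops reproduces hand-counted cases", {
  A <- matrix(0L, 3, 3)
  A[2, 1] <- A[3, 2] <- A[1, 3] <- 1L # directed 3-cycle
  expect_equal(count_loops(A, 3), 3)
  expect_equal(count_loops(A, 2), 0)

  B <- matrix(0L, 5, 5); B[1, 2] <- B[2, 1] <- 1L # one reciprocal pair
  expect_equal(count_loops(B, 2), 2)

  expect_equal(count_loops(matrix(0L, 4, 4), 2:6), rep(0, 5))
  expect_error(count_loops(A, 1), ">= 2")
})

test_that("count_loops equals the exhaustive closed-walk oracle for n <= 8", {
  for (seed in 1:12) {
    n <- 3 + seed %% 6
    A <- random_adjacency(n, 0.35, seed)
    for (len in 2:6) {
      oracle <- brute_force_loops(A, len)
      expect_identical(count_loops(A, len), as.double(oracle))
      expect_identical(count_loops(A, len, method = "double"),
                       as.double(oracle))
    }
  }
})

test_that("loop counts are invariant under node relabeling", {
  A <- random_adjacency(7, 0.4, 3)
  for (seed in 1:4) {
    perm <- with_local_seed(seed, sample(7))
    expect_equal(count_loops(A[perm, perm], 2:6), count_loops(A, 2:6))
  }
})

test_that("shuffle null preserves the weight multiset and the empty diagonal", {
  W <- random_weight_matrix(8, 1, seed = 2)
  sh <- shuffle_null(W, n_shuffles = 5, seed = 9)
  expect_length(sh, 5)
  off <- row(W) != col(W)
  for (S in sh) {
    expect_equal(sort(S[off]), sort(unclass(W)[off]))
    expect_true(all(diag(S) == 0))
  }
  expect_identical(shuffle_null(W, 3, seed = 7), shuffle_null(W, 3, seed = 7))
  expect_false(identical(sh[[1]], sh[[2]]))
})

test_that("loop ratios are near 1 for exchangeable weights and exactly 1 for equal weights", {
  W <- random_weight_matrix(40, 1, seed = 4)
  rep4 <- loop_ratio_report(W, "mean", lengths = 2:6, n_shuffles = 12, seed = 1)
  expect_true(all(abs(rep4$census$ratio - 1) < 0.2))
  expect_lt(abs(rep4$recurrence_index - 1), 0.2)

  Wc <- matrix(0.3, 10, 10); diag(Wc) <- 0
  repc <- loop_ratio_report(Wc, "mean", lengths = 2:5, n_shuffles = 3, seed = 1)
  expect_equal(repc$census$ratio, rep(1, 4))
})

test_that("planted reciprocal pairs raise the length-2 loop ratio above 1", {
  n <- 30
  W <- matrix(0, n, n)
  # background unidirectional edges keep the shuffle pool busy
  W[upper.tri(W)] <- with_local_seed(3, runif(sum(upper.tri(W))) < 0.1) * 1
  for (k in seq(1, 10, by = 2)) { W[k, k + 1] <- 1; W[k + 1, k] <- 1 }
  diag(W) <- 0
  rep2 <- loop_ratio_report(W, 0.5, lengths = 2, n_shuffles = 20, seed = 2)
  expect_gt(rep2$census$ratio[1], 1)
})

test_that("disconnected pairs are counted over unordered pairs", {
  expect_equal(disconnected_pairs(matrix(0, 4, 4), 0.5)$count, 6)
  Wf <- matrix(1, 4, 4); diag(Wf) <- 0
  expect_equal(disconnected_pairs(Wf, 0.5)$count, 0)
  W <- matrix(1, 4, 4); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 0.1 # one sub-threshold reciprocal pair
  expect_equal(disconnected_pairs(W, 0.5)$count, 1)
})

test_that("hub slope is -1 for a tournament and near 0 for i.i.d. weights", {
  n <- 20
  Wt <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (with_local_seed(i * n + j, runif(1)) < 0.5) Wt[j, i] <- 1
    else Wt[i, j] <- 1
  } # every pair resolved one way: in + out = n - 1 exactly
  hr <- hub_report(Wt, 0.5)
  expect_equal(hr$slope, -1, tolerance = 1e-10)

  Wr <- random_weight_matrix(60, 1, seed = 6)
  hr2 <- hub_report(Wr, "mean")
  expect_lt(abs(hr2$slope), 0.25)

  Wc <- matrix(0.4, 5, 5); diag(Wc) <- 0
  expect_false(hub_report(Wc, "mean")$slope_defined)
  expect_error(hub_report(matrix(0, 2, 2), 0.1), "3 neurons")
})
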