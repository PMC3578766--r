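#' Threshold a weight matrix into a directed adjacency matrix
#'
#' Entry `(i, j)` becomes 1 when the weight of the synapse j -> i is
#' greater than or equal to `theta` (Heaviside convention), 0 otherwise;
#' the diagonal is forced to zero. `theta = "mean"` resolves to the mean of
#' the off-diagonal weights, which removes the bias of overall weight
#' strength from loop counts.
#'
#' @param weights a [weight_matrix] or square numeric matrix.
#' @param theta threshold (mV, >= 0) or `"mean"`.
#' @return An object of class `adjacency_matrix` (integer matrix with a
#'   `theta` attribute).
#' @export
binarize <- function(weights, theta = "mean") {
  W <- unclass(as.matrix(weights))
  n <- nrow(W)
  if (ncol(W) != n) stop("weight matrix must be square")
  off <- W[row(W) != col(W)]
  if (identical(theta, "mean")) theta <- mean(off)
  stopifnot_scalar(theta, "theta")
  if (theta < 0) stop("theta must be >= 0")
  A <- matrix(0L, n, n)
  A[W >= theta] <- 1L
  diag(A) <- 0L
  structure(A, theta = theta, class = c("adjacency_matrix", "matrix", "array"))
}

#' Count closed loops of a given length
#'
#' Number of closed walks of length `L` in the directed graph, computed as
#' the trace of the L-th matrix power of the adjacency matrix (node
#' repetition allowed). The default method accumulates in 128-bit integer
#' arithmetic, which is exact for all supported sizes (n <= 500, L <= 9;
#' the guard errors beyond that). `method = "double"` uses floating-point
#' matrix products, exact below 2^53 and within about 1e-12 relative error
#' above it.
#'
#' @param adj an [adjacency_matrix] (or 0/1 matrix).
#' @param length loop length(s), each >= 2 (length-1 loops are impossible
#'   since self-connections are prohibited).
#' @param method `"exact"` or `"double"`.
#' @return Numeric vector of counts, one per requested length.
#' @export
count_loops <- function(adj, length, method = c("exact", "double")) {
  method <- match.arg(method)
  A <- unclass(as.matrix(adj))
  if (any(A != 0L & A != 1L)) stop("adjacency entries must be 0 or 1")
  if (any(length < 2)) stop("loop length must be >= 2")
  lmax <- max(length)
  if (method == "exact") {
    all_counts <- count_loops_exact_cpp(matrix(as.integer(A), nrow(A)), lmax)
  } else {
    all_counts <- numeric(lmax - 1)
    P <- A
    for (L in 2:lmax) {
      P <- P %*% A
      all_counts[L - 1] <- sum(diag(P))
    }
  }
  all_counts[length - 1]
}

#' Shuffle null model for a weight matrix
#'
#' Each shuffle applies a uniform random permutation to the off-diagonal
#' entries (the diagonal stays zero), preserving the weight multiset
#' exactly while destroying all structure. Deterministic given the seed.
#'
#' @param weights square numeric matrix.
#' @param n_shuffles number of shuffled copies (>= 1).
#' @param seed RNG seed.
#' @return List of shuffled matrices.
#' @export
shuffle_null <- function(weights, n_shuffles = 10, seed = 1) {
  W <- unclass(as.matrix(weights))
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  off <- row(W) != col(W)
  vals <- W[off]
  with_local_seed(seed, lapply(seq_len(n_shuffles), function(k) {
    S <- W
    S[off] <- sample(vals)
    S
  }))
}

#' Loop census with shuffle-null comparison
#'
#' Counts closed loops per length in the thresholded weight matrix and in
#' shuffled versions of the same matrix, and reports the ratio
#' real / mean(shuffled) per length together with the across-shuffle
#' standard deviation of the per-shuffle ratios. The recurrence index is
#' the total number of loops of lengths 2 through 9 divided by the same
#' total for the shuffled matrices.
#'
#' @param weights square numeric matrix (the plastic E-to-E weights).
#' @param theta threshold (mV) or `"mean"`.
#' @param lengths loop lengths to census.
#' @param n_shuffles number of shuffled matrices.
#' @param seed shuffle seed.
#' @return An object of class `loop_report`: data frame `census` (length,
#'   n_real, null_mean, null_sd, ratio, ratio_sd, defined flag),
#'   `recurrence_index`, and the shuffle bookkeeping.
#' @export
loop_ratio_report <- function(weights, theta = "mean", lengths = 2:9,
                              n_shuffles = 10, seed = 1) {
  A <- binarize(weights, theta)
  n_real <- count_loops(A, lengths)
  shuffles <- shuffle_null(weights, n_shuffles, seed)
  null_counts <- vapply(shuffles, function(S)
    count_loops(binarize(S, attr(A, "theta")), lengths), numeric(length(lengths)))
  null_counts <- matrix(null_counts, nrow = length(lengths))
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1, sd)
  defined <- null_mean > 0
  ratio <- ifelse(defined, n_real / null_mean, NA_real_)
  ratio_sd <- ifelse(defined,
                     apply(n_real / pmax(null_counts, 1e-300), 1, sd), NA_real_)
  ri_lengths <- 2:9
  ri_real <- count_loops(A, ri_lengths)
  ri_null <- rowMeans(matrix(vapply(shuffles, function(S)
    count_loops(binarize(S, attr(A, "theta")), ri_lengths),
    numeric(length(ri_lengths))), nrow = length(ri_lengths)))
  recurrence <- if (sum(ri_null) > 0) sum(ri_real) / sum(ri_null) else NA_real_
  structure(list(
    census = data.frame(length = lengths, n_real = n_real,
                        null_mean = null_mean, null_sd = null_sd,
                        ratio = ratio, ratio_sd = ratio_sd,
                        defined = defined),
    recurrence_index = recurrence,
    theta = attr(A, "theta"), n_shuffles = n_shuffles, seed = seed),
    class = "loop_report")
}

#' @export
print.loop_report <- function(x, ...) {
  cat(sprintf("Loop census (theta = %.4g mV, %d shuffles):\n",
              x$theta, x$n_shuffles))
  print(x$census, row.names = FALSE, digits = 4)
  cat(sprintf("Recurrence index (lengths 2-9): %.4g\n", x$recurrence_index))
  invisible(x)
}

#' Count disconnected neuron pairs
#'
#' Unordered pairs `{i, j}` whose two directed weights are both below the
#' threshold. Optionally compared against shuffled matrices.
#'
#' @param weights square numeric matrix.
#' @param theta threshold (mV) or `"mean"`.
#' @param n_shuffles if > 0, also report the ratio against the mean count
#'   over this many shuffles.
#' @param seed shuffle seed.
#' @return `list(count, ratio)`; `ratio` is NA when not requested or
#'   undefined.
#' @export
disconnected_pairs <- function(weights, theta = "mean", n_shuffles = 0,
                               seed = 1) {
  A <- binarize(weights, theta)
  count_disc <- function(B) {
    M <- B | t(B)
    sum(M[upper.tri(M)] == 0)
  }
  count <- count_disc(A)
  ratio <- NA_real_
  if (n_shuffles > 0) {
    nulls <- vapply(shuffle_null(weights, n_shuffles, seed), function(S)
      count_disc(binarize(S, attr(A, "theta"))), numeric(1))
    if (mean(nulls) > 0) ratio <- count / mean(nulls)
  }
  list(count = count, ratio = ratio)
}

#' In-/out-hub analysis of the thresholded network
#'
#' Per-neuron above-threshold in- and out-degrees and the ordinary
#' least-squares slope of in-degree regressed on out-degree. Balanced STDP
#' drives the network toward in + out = constant, i.e. a slope of -1.
#'
#' @param weights square numeric matrix.
#' @param theta threshold (mV) or `"mean"`.
#' @return An object of class `hub_report`: data frame `degrees`
#'   (`neuron`, `in_deg`, `out_deg`), `slope`, `intercept`, and
#'   `slope_defined` (FALSE when the out-degree has zero variance).
#' @export
hub_report <- function(weights, theta = "mean") {
  A <- binarize(weights, theta)
  n <- nrow(A)
  if (n < 3) stop("need at least 3 neurons")
  in_deg <- rowSums(A)   # (i, j) = j -> i: row sums are incoming
  out_deg <- colSums(A)
  slope <- NA_real_; intercept <- NA_real_
  defined <- var(out_deg) > 0
  if (defined) {
    fit <- lm(in_deg ~ out_deg)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  }
  structure(list(degrees = data.frame(neuron = seq_len(n), in_deg = in_deg,
                                      out_deg = out_deg),
                 slope = slope, intercept = intercept,
                 slope_defined = defined, theta = attr(A, "theta")),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hub analysis (theta = %.4g mV, %d neurons):\n",
              x$theta, nrow(x$degrees)))
  if (x$slope_defined) {
    cat(sprintf("  in-degree vs out-degree OLS slope %.3f (intercept %.2f)\n",
                x$slope, x$intercept))
  } else cat("  slope undefined (no out-degree variance)\n")
  invisible(x)
}
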