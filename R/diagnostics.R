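#' Average pairwise cross-covariance of spike trains
#'
#' Verifies the asynchronous operating regime assumed by the pairwise
#' analysis: spike trains of sampled excitatory neuron pairs are binned,
#' mean-subtracted, and their lagged covariance averaged over the sampled
#' ordered pairs. In the balanced state this average is close to zero at
#' all lags; shared-input correlations would show up as a central peak.
#'
#' @param raster a [spike_raster].
#' @param n_pairs number of ordered pairs to sample.
#' @param bin_ms bin size (ms).
#' @param max_lag_ms maximum lag (ms).
#' @param seed sampling seed.
#' @return An object of class `crosscov_report`: data frame `curve`
#'   (`lag_ms`, `avg_cov`, in squared spikes per bin), `n_pairs`, `bin_ms`,
#'   `duration_s`, and the mean inter-spike-interval coefficient of
#'   variation of the sampled neurons.
#' @export
cross_covariance <- function(raster, n_pairs = 100, bin_ms = 1,
                             max_lag_ms = 100, seed = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  if (bin_ms <= 0) stop("bin_ms must be positive")
  if (!nrow(raster$events)) stop("raster is empty")
  ne <- raster$n_exc
  active <- sort(unique(raster$events$neuron[raster$events$neuron <= ne]))
  if (length(active) < 2 ||
      n_pairs > length(active) * (length(active) - 1))
    stop("fewer active excitatory neurons than the requested pair sample needs")
  lag_bins <- round(max_lag_ms / bin_ms)
  breaks <- seq(raster$t_start_ms, raster$t_end_ms, by = bin_ms)
  nb <- length(breaks) - 1
  if (nb < 4 * lag_bins) stop("raster too short for the requested lags")
  pairs <- with_local_seed(seed, {
    all_pairs <- expand.grid(a = active, b = active)
    all_pairs <- all_pairs[all_pairs$a != all_pairs$b, ]
    all_pairs[sample(nrow(all_pairs), min(n_pairs, nrow(all_pairs))), ]
  })
  binned <- new.env(parent = emptyenv())
  get_bins <- function(id) {
    key <- as.character(id)
    if (is.null(binned[[key]])) {
      tt <- raster$events$time_ms[raster$events$neuron == id]
      x <- tabulate(findInterval(tt, breaks, rightmost.closed = TRUE), nbins = nb)
      binned[[key]] <- x - mean(x)
    }
    binned[[key]]
  }
  lags <- -lag_bins:lag_bins
  acc <- numeric(length(lags))
  for (k in seq_len(nrow(pairs))) {
    x <- get_bins(pairs$a[k]); y <- get_bins(pairs$b[k])
    cc <- vapply(lags, function(l) {
      if (l >= 0) mean(x[1:(nb - l)] * y[(1 + l):nb])
      else mean(x[(1 - l):nb] * y[1:(nb + l)])
    }, numeric(1))
    acc <- acc + cc
  }
  cv <- tryCatch(isi_cv(raster, n_sample = length(active), seed = seed),
                 error = function(e) NA_real_)
  structure(list(curve = data.frame(lag_ms = lags * bin_ms,
                                    avg_cov = acc / nrow(pairs)),
                 n_pairs = nrow(pairs), bin_ms = bin_ms,
                 duration_s = (raster$t_end_ms - raster$t_start_ms) / 1000,
                 cv_mean = cv),
            class = "crosscov_report")
}

#' @export
print.crosscov_report <- function(x, ...) {
  z <- x$curve$avg_cov[abs(x$curve$lag_ms) <= 10]
  cat(sprintf(
    "Cross-covariance over %d pairs (%g ms bins, %.3g s): central mean %.3g\n",
    x$n_pairs, x$bin_ms, x$duration_s, mean(z)))
  cat(sprintf("  mean ISI CV %.3f\n", x$cv_mean))
  invisible(x)
}

#' Mean inter-spike-interval coefficient of variation
#'
#' CV (ISI standard deviation over ISI mean) averaged over sampled
#' excitatory neurons; neurons with fewer than 3 spikes are skipped and
#' counted. A homogeneous Poisson train has CV near 1; perfectly periodic
#' firing gives 0.
#'
#' @param raster a [spike_raster].
#' @param n_sample number of excitatory neurons to sample.
#' @param seed sampling seed.
#' @return Mean CV with attribute `n_skipped`.
#' @export
isi_cv <- function(raster, n_sample = 100, seed = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  ne <- raster$n_exc
  ids <- with_local_seed(seed, sample(seq_len(ne), min(n_sample, ne)))
  cvs <- numeric(0); skipped <- 0L
  for (id in ids) {
    tt <- raster$events$time_ms[raster$events$neuron == id]
    if (length(tt) < 3) { skipped <- skipped + 1L; next }
    isi <- diff(tt)
    cvs <- c(cvs, sd(isi) / mean(isi))
  }
  if (!length(cvs)) stop("no sampled neuron has >= 3 spikes")
  structure(mean(cvs), n_skipped = skipped)
}
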