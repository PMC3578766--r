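#' LIF neuron parameters
#'
#' Membrane dynamics follow `tau_m dV/dt = -(V - v_rest) + I(t)`; when `V`
#' reaches `v_thresh` a spike is emitted and the membrane resets to the
#' resting value (reset equals rest in this model). Synaptic input is
#' measured in membrane-potential units (mV), the membrane resistance being
#' absorbed into the weights.
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest resting (and reset) potential (mV).
#' @param v_thresh firing threshold (mV), must exceed `v_rest`.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, v_rest = -60, v_thresh = -50) {
  stopifnot_scalar(tau_m, "tau_m", positive = TRUE)
  stopifnot_scalar(v_rest, "v_rest")
  stopifnot_scalar(v_thresh, "v_thresh")
  if (v_thresh <= v_rest) stop("v_thresh must exceed v_rest")
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_rest),
            class = "neuron_params")
}

#' Recurrent network parameters
#'
#' An all-to-all network (self-connections prohibited) of `n_exc` excitatory
#' and `n_inh` inhibitory LIF neurons. Excitatory-to-excitatory synapses are
#' plastic with hard bounds `[0, w_max_ee]`; the remaining blocks are fixed,
#' drawn uniformly on `[0, bound]` at initialization. The
#' inhibitory-to-excitatory and inhibitory-to-inhibitory bounds are equal by
#' construction (equally strong inhibition onto both populations), and
#' inhibition is stronger than excitation so that the network settles into
#' an excitation/inhibition balanced state with asynchronous irregular
#' firing. Each neuron additionally receives a constant bias `mu` and
#' independent Gaussian white noise of amplitude `sigma`.
#'
#' @param n_exc,n_inh population sizes.
#' @param tau_s synaptic decay time constant (ms).
#' @param w_max_ee upper hard bound of the plastic E-to-E weights (mV).
#' @param w_ei_max uniform-init upper bound, E-to-I block (mV).
#' @param w_ie_max uniform-init upper bound, I-to-E block (mV).
#' @param w_ii_max uniform-init upper bound, I-to-I block (mV); must equal
#'   `w_ie_max`.
#' @param mu external bias common to all neurons (mV).
#' @param sigma white-noise amplitude (mV sqrt(ms)).
#' @param dt integration step (ms).
#' @param seed master PRNG seed; each neuron derives an independent stream.
#' @return An object of class `network_params`.
#' @export
network_params <- function(n_exc = 500, n_inh = 250, tau_s = 5,
                           w_max_ee = 0.8, w_ei_max = 0.8,
                           w_ie_max = 6, w_ii_max = 6,
                           mu = 86, sigma = 30, dt = 0.1, seed = 1) {
  stopifnot(n_exc >= 1, n_inh >= 1)
  stopifnot_scalar(tau_s, "tau_s", positive = TRUE)
  stopifnot_scalar(w_max_ee, "w_max_ee", positive = TRUE)
  stopifnot_scalar(w_ei_max, "w_ei_max", positive = TRUE)
  stopifnot_scalar(w_ie_max, "w_ie_max", positive = TRUE)
  stopifnot_scalar(w_ii_max, "w_ii_max", positive = TRUE)
  if (w_ie_max != w_ii_max)
    stop("inhibitory-to-excitatory and inhibitory-to-inhibitory bounds must be equal")
  stopifnot_scalar(dt, "dt", positive = TRUE)
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 tau_s = tau_s, w_max_ee = w_max_ee, w_ei_max = w_ei_max,
                 w_ie_max = w_ie_max, w_ii_max = w_ii_max,
                 mu = mu, sigma = sigma, dt = dt, seed = seed),
            class = "network_params")
}

#' Plastic E-to-E weight matrix
#'
#' Entry `(i, j)` is the strength (mV) of the synapse from neuron `j` onto
#' neuron `i`. The diagonal is zero (no self-connections) and every entry
#' lies in `[0, w_max]`.
#'
#' @param entries square numeric matrix.
#' @param w_max upper hard bound (mV).
#' @return An object of class `weight_matrix` (a matrix with a `w_max`
#'   attribute).
#' @export
weight_matrix <- function(entries, w_max) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) stop("weight matrix must be square")
  if (any(diag(entries) != 0)) stop("self connections are prohibited (nonzero diagonal)")
  if (any(entries < 0) || any(entries > w_max))
    stop("weights must lie in [0, w_max]")
  structure(entries, w_max = w_max, class = c("weight_matrix", "matrix", "array"))
}

#' Draw a random initial E-to-E weight matrix
#'
#' Off-diagonal entries i.i.d. uniform on `[0, w_max]`, zero diagonal.
#'
#' @param n_exc number of excitatory neurons.
#' @param w_max upper bound (mV).
#' @param seed RNG seed.
#' @export
random_weight_matrix <- function(n_exc, w_max, seed = 1) {
  W <- with_local_seed(seed, matrix(runif(n_exc * n_exc, 0, w_max), n_exc))
  diag(W) <- 0
  weight_matrix(W, w_max)
}

#' Spike raster
#'
#' @param time_ms event times (ms), sorted ascending.
#' @param neuron 1-based neuron ids (1..n_exc are excitatory, the rest
#'   inhibitory).
#' @param t_start_ms,t_end_ms time span covered by the raster (ms).
#' @param n_exc,n_inh population sizes.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(time_ms, neuron, t_start_ms, t_end_ms, n_exc, n_inh = 0) {
  if (length(time_ms) != length(neuron)) stop("times and ids differ in length")
  if (is.unsorted(time_ms)) stop("spike times must be sorted")
  n <- n_exc + n_inh
  if (length(neuron) && (min(neuron) < 1 || max(neuron) > n))
    stop("invalid neuron ids")
  if (length(time_ms) && (min(time_ms) < t_start_ms - 1e-9 ||
                          max(time_ms) > t_end_ms + 1e-9))
    stop("spike times outside raster span")
  structure(list(events = data.frame(time_ms = time_ms,
                                     neuron = as.integer(neuron)),
                 t_start_ms = t_start_ms, t_end_ms = t_end_ms,
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  dur_s <- (x$t_end_ms - x$t_start_ms) / 1000
  cat(sprintf("Spike raster: %d events, %d E + %d I neurons, %.3g s\n",
              nrow(x$events), x$n_exc, x$n_inh, dur_s))
  if (nrow(x$events) && x$n_exc > 0) {
    e <- x$events$neuron <= x$n_exc
    cat(sprintf("  mean E rate %.2f Hz\n", sum(e) / x$n_exc / dur_s))
  }
  invisible(x)
}

#' Mean firing rate of a raster
#'
#' @param raster a [spike_raster].
#' @param population `"exc"`, `"inh"` or `"all"`.
#' @param from_ms count spikes from this time onward (default: whole span).
#' @return Mean rate per neuron (Hz).
#' @export
mean_rate <- function(raster, population = c("exc", "inh", "all"),
                      from_ms = raster$t_start_ms) {
  population <- match.arg(population)
  ids <- switch(population,
                exc = seq_len(raster$n_exc),
                inh = raster$n_exc + seq_len(raster$n_inh),
                all = seq_len(raster$n_exc + raster$n_inh))
  ev <- raster$events
  k <- sum(ev$neuron %in% ids & ev$time_ms >= from_ms)
  k / length(ids) / ((raster$t_end_ms - from_ms) / 1000)
}

build_full_weights <- function(params, initial_weights, seed) {
  ne <- params$n_exc; ni <- params$n_inh; n <- ne + ni
  if (is.null(initial_weights)) {
    initial_weights <- random_weight_matrix(ne, params$w_max_ee,
                                            derive_seed(seed, 11L))
  } else {
    if (!inherits(initial_weights, "weight_matrix"))
      initial_weights <- weight_matrix(initial_weights, params$w_max_ee)
    if (nrow(initial_weights) != ne)
      stop("initial_weights dimension does not match n_exc")
    if (attr(initial_weights, "w_max") != params$w_max_ee)
      stop("initial_weights bound does not match params$w_max_ee")
  }
  W <- matrix(0, n, n)
  W[seq_len(ne), seq_len(ne)] <- unclass(initial_weights)
  with_local_seed(derive_seed(seed, 12L), {
    W[ne + seq_len(ni), seq_len(ne)] <- runif(ni * ne, 0, params$w_ei_max)
    W[seq_len(ne), ne + seq_len(ni)] <- runif(ne * ni, 0, params$w_ie_max)
    W[ne + seq_len(ni), ne + seq_len(ni)] <- runif(ni * ni, 0, params$w_ii_max)
  })
  diag(W) <- 0
  W
}

#' Simulate the recurrent LIF network
#'
#' Fixed-step (forward Euler / Euler-Maruyama) integration of the network.
#' Synaptic input decays exponentially with `tau_s` between arrivals and
#' jumps by the connecting weight at each presynaptic spike (excitatory
#' positive, inhibitory negative) with a one-step axonal latency. When
#' `plasticity` is on, every E-to-E synapse is updated under the window's
#' pairing scheme with hard bounds applied at every update; when off, the
#' returned weights equal the initial weights bit-exactly. Identical seeds
#' give identical outputs.
#'
#' @param params a [network_params].
#' @param neuron a [neuron_params].
#' @param window an [stdp_window]; required when `plasticity = TRUE`. Its
#'   `w_max` must equal `params$w_max_ee`.
#' @param initial_weights E-to-E [weight_matrix] (or plain matrix); drawn
#'   uniformly from the seed when omitted.
#' @param duration_s simulated time (s).
#' @param plasticity logical; freeze the E-to-E weights when `FALSE`.
#' @param mu bias override: scalar or per-neuron vector (mV); defaults to
#'   `params$mu`.
#' @param seed master seed (defaults to `params$seed`).
#' @param record_dt_s sampling interval of the summary record (s).
#' @param spike_record_start_s only spikes from this (relative) time on are
#'   stored in the raster; counts are always complete.
#' @param state warm-start state from a previous call (chunked runs).
#' @param chunk chunk index; advancing it gives each continuation fresh
#'   per-neuron noise streams.
#' @return An object of class `lif_sim` with elements `raster`
#'   ([spike_raster]), `weights` (final E-to-E [weight_matrix]), `record`
#'   (data frame `time_s`, `rate_hz`, `w_mean`, `w_var`), `counts`
#'   (neuron-by-window spike counts), and `state` for continuation.
#' @export
simulate_network <- function(params, neuron = neuron_params(), window = NULL,
                             initial_weights = NULL, duration_s,
                             plasticity = TRUE, mu = NULL,
                             seed = params$seed, record_dt_s = 1,
                             spike_record_start_s = 0,
                             state = NULL, chunk = 0) {
  stopifnot(inherits(params, "network_params"), inherits(neuron, "neuron_params"))
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  ne <- params$n_exc; ni <- params$n_inh; n <- ne + ni
  if (plasticity) {
    if (!inherits(window, "stdp_window"))
      stop("plasticity = TRUE requires an stdp_window")
    if (window$w_max != params$w_max_ee)
      stop("window$w_max must equal params$w_max_ee")
  }
  mu <- mu %||% params$mu
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (length(mu) != n) stop("mu must be scalar or length n_exc + n_inh")

  if (is.null(state)) {
    W <- build_full_weights(params, initial_weights, seed)
    t0 <- 0
    cpp_state <- NULL
  } else {
    W <- state$W_full
    t0 <- state$t_end_ms
    cpp_state <- state$cpp
  }

  win <- window %||% stdp_window(1e-6, 1e-6, 20, 20, 0, "all_to_all",
                                 params$w_max_ee)
  res <- sim_network_cpp(
    ne, ni, W, mu, params$sigma,
    neuron$tau_m, neuron$v_rest, neuron$v_thresh, params$tau_s,
    params$dt, duration_s * 1000, t0,
    plasticity,
    win$a_plus, win$a_minus, win$tau_plus, win$tau_minus,
    win$shift, win$pairing == "nearest_neighbor", params$w_max_ee,
    record_dt_s * 1000, t0 + spike_record_start_s * 1000,
    as.double(seed), as.double(chunk), cpp_state)

  rate_hz <- colSums(res$counts[seq_len(ne), , drop = FALSE]) / ne / record_dt_s
  record <- data.frame(time_s = res$win_end_ms / 1000, rate_hz = rate_hz,
                       w_mean = res$w_mean, w_var = res$w_var)
  raster <- spike_raster(res$spike_t, res$spike_id,
                         t_start_ms = t0 + spike_record_start_s * 1000,
                         t_end_ms = t0 + duration_s * 1000,
                         n_exc = ne, n_inh = ni)
  structure(list(
    raster = raster,
    weights = weight_matrix(res$W[seq_len(ne), seq_len(ne)], params$w_max_ee),
    record = record, counts = res$counts,
    state = list(W_full = res$W, t_end_ms = t0 + duration_s * 1000,
                 cpp = res$state),
    params = params, neuron = neuron, window = window,
    plasticity = plasticity, seed = seed), class = "lif_sim")
}

#' @export
print.lif_sim <- function(x, ...) {
  rec <- x$record
  cat(sprintf("LIF network simulation: %d E + %d I, %.3g s, plasticity %s\n",
              x$params$n_exc, x$params$n_inh,
              max(rec$time_s) - min(rec$time_s) + rec$time_s[1],
              if (x$plasticity) "on" else "off"))
  cat(sprintf("  final window: rate %.2f Hz, mean E-E weight %.4f mV\n",
              rec$rate_hz[nrow(rec)], rec$w_mean[nrow(rec)]))
  invisible(x)
}

#' Run a plastic network until the weights reach steady state
#'
#' Simulates in chunks and stops when the mean firing rate, the mean E-to-E
#' weight and the weight variance all have trailing-window drifts below
#' `slope_tol` (see [detect_steady_state()]), or when `max_duration_s` is
#' reached. Only the final chunk's spikes are kept in the raster.
#'
#' @inheritParams simulate_network
#' @param chunk_s chunk length (s).
#' @param max_duration_s time budget (s).
#' @param ss_window_s trailing analysis window for the steady-state test (s).
#' @param slope_tol relative per-window drift tolerance.
#' @return An `lif_sim` with extra fields `converged` (logical) and
#'   `convergence_time_s`.
#' @export
simulate_until_steady <- function(params, neuron = neuron_params(), window,
                                  initial_weights = NULL, mu = NULL,
                                  seed = params$seed,
                                  chunk_s = 50, max_duration_s = 600,
                                  ss_window_s = 40, slope_tol = 0.05,
                                  record_dt_s = 2) {
  state <- NULL
  record <- NULL
  counts <- NULL
  sim <- NULL
  t_done <- 0
  chunk <- 0
  converged <- FALSE
  conv_time <- NA_real_
  while (t_done < max_duration_s) {
    len <- min(chunk_s, max_duration_s - t_done)
    sim <- simulate_network(params, neuron, window, initial_weights,
                            duration_s = len, plasticity = TRUE, mu = mu,
                            seed = seed, record_dt_s = record_dt_s,
                            spike_record_start_s = 0,
                            state = state, chunk = chunk)
    record <- rbind(record, sim$record)
    counts <- cbind(counts, sim$counts)
    state <- sim$state
    t_done <- t_done + len
    chunk <- chunk + 1
    if (max(record$time_s) - min(record$time_s) >= 2 * ss_window_s) {
      ss <- detect_steady_state(record, window_s = ss_window_s,
                                slope_tol = slope_tol)
      if (ss$converged) { converged <- TRUE; conv_time <- ss$time_s; break }
    }
  }
  sim$record <- record
  sim$counts <- counts
  sim$converged <- converged
  sim$convergence_time_s <- conv_time
  sim
}

#' Detect steady state in a simulation record
#'
#' The network is declared stationary at the first sample time whose
#' trailing window of length `window_s` shows, for each of the mean firing
#' rate, the mean weight and the weight variance, a fitted linear drift
#' whose change over one window is below `slope_tol` relative to the
#' series' level.
#'
#' @param record data frame with columns `time_s`, `rate_hz`, `w_mean`,
#'   `w_var` (as produced by [simulate_network()]).
#' @param window_s analysis window length (s).
#' @param slope_tol relative per-window drift tolerance.
#' @return `list(converged = logical, time_s = first qualifying time or NA)`.
#' @export
detect_steady_state <- function(record, window_s = 40, slope_tol = 0.05) {
  need <- c("time_s", "rate_hz", "w_mean", "w_var")
  if (!all(need %in% names(record))) stop("record lacks required columns")
  t <- record$time_s
  if (length(t) < 3) stop("record too short")
  rec_dt <- stats::median(diff(t))
  t_origin <- t[1] - rec_dt
  if (max(t) - t_origin < window_s) stop("record shorter than one analysis window")
  series <- record[c("rate_hz", "w_mean", "w_var")]
  scale_all <- vapply(series, function(s) max(abs(s)), numeric(1))
  for (i in seq_along(t)) {
    if (t[i] - t_origin < window_s) next
    sel <- t > t[i] - window_s + 1e-9 & t <= t[i] + 1e-9
    if (sum(sel) < 3) next
    ok <- TRUE
    for (k in seq_along(series)) {
      s <- series[[k]][sel]
      b <- coef(lm(s ~ t[sel]))[2]
      denom <- max(abs(mean(s)), 0.05 * scale_all[k], 1e-12)
      if (abs(b) * window_s / denom >= slope_tol) { ok <- FALSE; break }
    }
    if (ok) return(list(converged = TRUE, time_s = t[i]))
  }
  list(converged = FALSE, time_s = NA_real_)
}

#' Calibrate the external bias to a target firing rate
#'
#' Finds the common bias `mu` at which the network's mean excitatory rate
#' (plasticity frozen, measured over a probe run after a discard period)
#' is within `tolerance` of `target_rate`. The mean rate is increasing in
#' the bias, so the root is bracketed and bisected. Deterministic given the
#' seed.
#'
#' @inheritParams simulate_network
#' @param target_rate target mean excitatory rate (Hz, > 0).
#' @param tolerance acceptable rate error (Hz).
#' @param probe_s probe duration (s).
#' @param discard_s initial transient excluded from the rate estimate (s).
#' @param mu_range search interval for the bias (mV).
#' @param max_iter bisection iteration cap.
#' @return The calibrated bias (mV) with attribute `rate_hz`, the probe
#'   rate achieved.
#' @export
calibrate_bias <- function(params, neuron = neuron_params(),
                           target_rate, tolerance = 1,
                           initial_weights = NULL, seed = params$seed,
                           probe_s = 6, discard_s = 1,
                           mu_range = c(0, 300), max_iter = 24) {
  stopifnot_scalar(target_rate, "target_rate")
  if (target_rate <= 0) stop("target_rate must be positive (non-bracketable)")
  key <- cache_key("cal", unlist(params), unlist(neuron), target_rate,
                   tolerance, seed, probe_s, discard_s, mu_range)
  if (!is.null(.stdpnet_cache[[key]])) return(.stdpnet_cache[[key]])
  W0 <- build_full_weights(params, initial_weights, seed)
  Wee <- weight_matrix(W0[seq_len(params$n_exc), seq_len(params$n_exc)],
                       params$w_max_ee)
  probe <- function(mu) {
    sim <- simulate_network(params, neuron, window = NULL,
                            initial_weights = Wee, duration_s = probe_s,
                            plasticity = FALSE, mu = mu, seed = seed,
                            record_dt_s = 0.5, spike_record_start_s = probe_s)
    mean(sim$record$rate_hz[sim$record$time_s > discard_s])
  }
  lo <- mu_range[1]; hi <- mu_range[2]
  r_lo <- probe(lo); r_hi <- probe(hi)
  if (r_lo > target_rate || r_hi < target_rate)
    stop(sprintf(
      "calibration failure: target %.3g Hz not bracketable in mu range [%g, %g] (rates %.3g..%.3g Hz)",
      target_rate, lo, hi, r_lo, r_hi))
  mu <- (lo + hi) / 2; r <- probe(mu)
  for (it in seq_len(max_iter)) {
    if (abs(r - target_rate) <= tolerance) break
    if (r < target_rate) lo <- mu else hi <- mu
    mu <- (lo + hi) / 2
    r <- probe(mu)
  }
  if (abs(r - target_rate) > tolerance)
    stop(sprintf("calibration failure: rate %.3g Hz vs target %.3g Hz after %d iterations",
                 r, target_rate, max_iter))
  out <- structure(mu, rate_hz = r)
  .stdpnet_cache[[key]] <- out
  out
}

#' Offline replay of STDP over a recorded raster
#'
#' Accumulates pairwise weight changes from a spike raster by replaying the
#' events in order, mirroring the online bookkeeping exactly: per spike
#' event, incoming potentiation is applied before outgoing depression
#' (all-to-all, via exponentially decaying traces) or last-spike-register
#' pairings (nearest-neighbor), with hard bounds applied after each
#' aggregated update and simultaneous spikes handled through the dt = 0
#' convention. Used to verify the online implementation.
#'
#' @param raster a [spike_raster]; only excitatory spikes drive plasticity.
#' @param window an [stdp_window].
#' @param initial_weights E-to-E [weight_matrix].
#' @return The final E-to-E weight matrix after replay.
#' @export
replay_stdp <- function(raster, window, initial_weights) {
  stopifnot(inherits(raster, "spike_raster"), inherits(window, "stdp_window"))
  ne <- raster$n_exc
  W <- unclass(initial_weights)
  w_max <- attr(initial_weights, "w_max")
  ev <- raster$events
  ev <- ev[ev$neuron <= ne, , drop = FALSE]
  if (!nrow(ev)) return(weight_matrix(W, w_max))
  nn <- window$pairing == "nearest_neighbor"
  xval <- numeric(ne); xt <- rep(-Inf, ne)
  yval <- numeric(ne); yt <- rep(-Inf, ne)
  last <- rep(-Inf, ne)
  clip <- function(w) pmin(w_max, pmax(0, w))
  times <- unique(ev$time_ms)
  for (t in times) {
    sp <- sort(ev$neuron[ev$time_ms == t])
    in_group <- logical(ne); in_group[sp] <- TRUE
    for (i in sp) {
      if (!nn) {
        xs <- ifelse(is.finite(xt), xval * exp(-(t - xt) / window$tau_plus), 0)
        ys <- ifelse(is.finite(yt), yval * exp(-(t - yt) / window$tau_minus), 0)
        js <- setdiff(seq_len(ne), i)
        W[i, js] <- clip(W[i, js] + window$a_plus * xs[js])
        W[js, i] <- clip(W[js, i] - window$a_minus * ys[js])
      } else {
        for (j in seq_len(ne)) {
          if (j == i) next
          if (in_group[j]) {
            W[i, j] <- clip(W[i, j] + window_value(0, window))
          } else if (is.finite(last[j])) {
            W[i, j] <- clip(W[i, j] + window_value(t - last[j], window))
            W[j, i] <- clip(W[j, i] + window_value(last[j] - t, window))
          }
        }
      }
    }
    for (i in sp) {
      if (!nn) {
        xval[i] <- (if (is.finite(xt[i]))
          xval[i] * exp(-(t - xt[i]) / window$tau_plus) else 0) + 1
        yval[i] <- (if (is.finite(yt[i]))
          yval[i] * exp(-(t - yt[i]) / window$tau_minus) else 0) + 1
        xt[i] <- t; yt[i] <- t
      } else last[i] <- t
    }
  }
  weight_matrix(W, w_max)
}
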