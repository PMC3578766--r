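#' STDP window parameters
#'
#' Defines the pair-based STDP rule: a weight change `+a_plus *
#' exp(-(dt - shift)/tau_plus)` when the pairing interval `dt = t_post -
#' t_pre` lies at or beyond the window boundary `shift`, and `-a_minus *
#' exp((dt - shift)/tau_minus)` below it. With `shift = 0` this is the
#' conventional antisymmetric window; a positive shift means that
#' near-coincident spikes (`0 < dt < shift`) depress the synapse, a negative
#' shift that they potentiate it. Weights evolve under hard bounds on
#' `[0, w_max]`.
#'
#' Shifted windows (`shift != 0`) require nearest-neighbor pairing; this is
#' enforced here because all-to-all interactions are unstable for shifted
#' windows.
#'
#' @param a_plus maximum potentiation amplitude (mV, > 0).
#' @param a_minus maximum depression amplitude (mV, > 0).
#' @param tau_plus potentiation time constant (ms, > 0).
#' @param tau_minus depression time constant (ms, > 0).
#' @param shift temporal shift of the window boundary (ms, signed).
#' @param pairing spike-pairing scheme, `"all_to_all"` or
#'   `"nearest_neighbor"`.
#' @param w_max upper hard bound on the synaptic weight (mV, > 0); the lower
#'   bound is always 0.
#' @return An object of class `stdp_window`.
#' @examples
#' w <- stdp_window(0.01, 0.01, 20, 20)
#' window_value(c(-10, 10), w)
#' @export
stdp_window <- function(a_plus, a_minus, tau_plus = 20, tau_minus = 20,
                        shift = 0,
                        pairing = c("all_to_all", "nearest_neighbor"),
                        w_max = 0.5) {
  pairing <- match.arg(pairing)
  stopifnot_scalar(a_plus, "a_plus", positive = TRUE)
  stopifnot_scalar(a_minus, "a_minus", positive = TRUE)
  stopifnot_scalar(tau_plus, "tau_plus", positive = TRUE)
  stopifnot_scalar(tau_minus, "tau_minus", positive = TRUE)
  stopifnot_scalar(shift, "shift")
  stopifnot_scalar(w_max, "w_max", positive = TRUE)
  if (shift != 0 && pairing != "nearest_neighbor")
    stop("shifted windows (shift != 0) require nearest_neighbor pairing")
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 shift = shift, pairing = pairing, w_max = w_max),
            class = "stdp_window")
}

#' @export
print.stdp_window <- function(x, ...) {
  cat("STDP window:",
      sprintf("A+ = %.4g mV, A- = %.4g mV, tau+ = %g ms, tau- = %g ms",
              x$a_plus, x$a_minus, x$tau_plus, x$tau_minus), "\n")
  cat(sprintf("  shift d = %g ms, pairing = %s, hard bounds [0, %g] mV\n",
              x$shift, x$pairing, x$w_max))
  invisible(x)
}

#' Evaluate the STDP window
#'
#' Weight change induced by a single pre/post spike pair at pairing
#' interval `dt = t_post - t_pre` (ms; positive when the presynaptic spike
#' leads). The boundary case `dt == shift` is assigned to the potentiation
#' branch; for an unshifted window, exactly simultaneous spikes (`dt == 0`)
#' contribute zero, preserving the window's odd symmetry.
#'
#' @param dt pairing interval(s) in ms; must be finite.
#' @param window an [stdp_window].
#' @return Numeric vector of weight changes (mV), same length as `dt`.
#' @export
window_value <- function(dt, window) {
  stopifnot(inherits(window, "stdp_window"))
  if (!is.numeric(dt) || any(!is.finite(dt)))
    stop("'dt' must be finite numeric")
  d <- window$shift
  out <- ifelse(dt >= d,
                window$a_plus * exp(-(dt - d) / window$tau_plus),
                -window$a_minus * exp((dt - d) / window$tau_minus))
  if (d == 0) out[dt == 0] <- 0
  out
}

#' Enumerate pre/post spike pairings
#'
#' Builds the set of pairing events between a presynaptic and a postsynaptic
#' spike train under either interaction scheme. All-to-all returns the full
#' Cartesian set. The nearest-neighbor scheme is the reduced symmetric rule:
#' each postsynaptic spike pairs with the most recent presynaptic spike
#' preceding-or-at it, and each presynaptic spike pairs with the most recent
#' postsynaptic spike preceding-or-at it; a pair arising from both sides at
#' an exact tie (`dt = 0`) is counted once. This rule is exactly what an
#' online implementation with last-spike-time registers produces.
#'
#' @param pre_times,post_times sorted ascending spike times (ms), no
#'   duplicates within a train.
#' @param scheme `"all_to_all"` or `"nearest_neighbor"`.
#' @return A data frame with columns `dt` (ms, `t_post - t_pre`),
#'   `pre_index`, `post_index`. Empty trains yield zero rows.
#' @export
pair_spikes <- function(pre_times, post_times,
                        scheme = c("all_to_all", "nearest_neighbor")) {
  scheme <- match.arg(scheme)
  check_train <- function(x, name) {
    if (length(x) == 0L) return(invisible())
    if (any(!is.finite(x))) stop(sprintf("'%s' must be finite", name))
    if (is.unsorted(x, strictly = TRUE))
      stop(sprintf("'%s' must be strictly ascending", name))
  }
  check_train(pre_times, "pre_times")
  check_train(post_times, "post_times")
  empty <- data.frame(dt = numeric(0), pre_index = integer(0),
                      post_index = integer(0))
  if (length(pre_times) == 0L || length(post_times) == 0L) return(empty)

  if (scheme == "all_to_all") {
    g <- expand.grid(pre_index = seq_along(pre_times),
                     post_index = seq_along(post_times))
    return(data.frame(dt = post_times[g$post_index] - pre_times[g$pre_index],
                      pre_index = g$pre_index, post_index = g$post_index))
  }

  # nearest neighbor: last pre at-or-before each post, and vice versa
  pre_for_post <- findInterval(post_times, pre_times)     # 0 if none
  post_for_pre <- findInterval(pre_times, post_times)
  a <- data.frame(pre_index = pre_for_post,
                  post_index = seq_along(post_times))
  a <- a[a$pre_index > 0L, , drop = FALSE]
  b <- data.frame(pre_index = seq_along(pre_times),
                  post_index = post_for_pre)
  b <- b[b$post_index > 0L, , drop = FALSE]
  ev <- unique(rbind(a, b))
  ev <- ev[order(ev$post_index, ev$pre_index), , drop = FALSE]
  rownames(ev) <- NULL
  data.frame(dt = post_times[ev$post_index] - pre_times[ev$pre_index],
             pre_index = ev$pre_index, post_index = ev$post_index)
}

#' Apply a weight update under hard bounds
#'
#' @param w current weight (mV), must lie in `[0, w_max]`.
#' @param delta proposed weight change (mV).
#' @param window an [stdp_window] supplying `w_max`.
#' @return The clipped weight `min(w_max, max(0, w + delta))`.
#' @export
apply_hard_bounds <- function(w, delta, window) {
  stopifnot(inherits(window, "stdp_window"))
  if (any(w < 0 | w > window$w_max))
    stop("weight outside [0, w_max] on entry")
  pmin(window$w_max, pmax(0, w + delta))
}

#' Serialize an STDP window to JSON
#'
#' Flat JSON object with keys `a_plus`, `a_minus`, `tau_plus`, `tau_minus`,
#' `shift_ms`, `pairing`, `w_max`.
#'
#' @param window an [stdp_window].
#' @param path optional file to write to.
#' @return The JSON string, invisibly if written to file.
#' @export
window_to_json <- function(window, path = NULL) {
  stopifnot(inherits(window, "stdp_window"))
  obj <- list(a_plus = window$a_plus, a_minus = window$a_minus,
              tau_plus = window$tau_plus, tau_minus = window$tau_minus,
              shift_ms = window$shift, pairing = window$pairing,
              w_max = window$w_max)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read an STDP window from JSON
#'
#' @param path file, or a JSON string, as written by [window_to_json()].
#' @return An [stdp_window].
#' @export
window_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  stdp_window(a_plus = obj$a_plus, a_minus = obj$a_minus,
              tau_plus = obj$tau_plus, tau_minus = obj$tau_minus,
              shift = obj$shift_ms, pairing = obj$pairing,
              w_max = obj$w_max)
}
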