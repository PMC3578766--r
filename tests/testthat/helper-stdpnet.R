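# Shared fixtures and independent oracles for the test suite.

# Tiny network whose fixed synaptic blocks are effectively absent, so a
# neuron's dynamics reduce to the bias + noise terms.
isolated_params <- function(n_exc = 3, n_inh = 2, mu = 8, sigma = 0,
                            seed = 1, w_max_ee = 0.8) {
  network_params(n_exc = n_exc, n_inh = n_inh, w_max_ee = w_max_ee,
                 w_ei_max = 1e-12, w_ie_max = 1e-12, w_ii_max = 1e-12,
                 mu = mu, sigma = sigma, seed = seed)
}

zero_weights <- function(n, w_max = 0.8) weight_matrix(matrix(0, n, n), w_max)

# Exhaustive closed-walk count by depth-first enumeration; edge a -> b
# exists iff A[b, a] == 1 (postsynaptic row convention). Exponential in
# length, usable only for small graphs -- which is the point: it shares
# nothing with the trace-of-matrix-powers implementation.
brute_force_loops <- function(A, len) {
  n <- nrow(A)
  walk <- function(start, v, remaining) {
    if (remaining == 0L) return(as.integer(v == start))
    nxt <- which(A[, v] == 1L)
    if (!length(nxt)) return(0L)
    sum(vapply(nxt, function(b) walk(start, b, remaining - 1L), integer(1)))
  }
  sum(vapply(seq_len(n), function(v) walk(v, v, len), integer(1)))
}

random_adjacency <- function(n, p, seed) {
  A <- with_local_seed(seed, matrix(as.integer(runif(n * n) < p), n))
  diag(A) <- 0L
  A
}

with_local_seed <- stdpnet:::with_local_seed
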