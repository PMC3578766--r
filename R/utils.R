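`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the R RNG temporarily seeded, restoring any prior state.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive a well-spread 31-bit child seed from (seed, stream index).
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 2654435761 + as.double(stream) * 40503) %% 2147483647
  as.integer(s) + 1L
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

cache_key <- function(...) paste(vapply(list(...), function(x)
  paste(format(x, digits = 12), collapse = ","), character(1)), collapse = "|")
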