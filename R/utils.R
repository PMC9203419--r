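# Internal numerical helpers.

# log(sum(exp(x))) guarded against -Inf and overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gumbel-max categorical draw from unnormalised log probabilities.
sample_log_categorical <- function(logp) {
  g <- -log(-log(stats::runif(length(logp))))
  which.max(logp + g)
}

# Deterministic 31-bit seed for a (master seed, stream) pair; keeps every
# derived seed a valid R integer.
derive_seed <- function(master, stream) {
  s <- (as.double(master) %% 2147483647)
  for (x in as.double(stream)) {
    s <- (s * 48271 + x + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(TRUE)
}
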