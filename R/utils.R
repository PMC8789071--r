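# Internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL means "use the ambient RNG stream".
run_seeded <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Table-style rounding: halves away from zero.
round_half_up <- function(x) floor(x + 0.5)

# Slope/intercept least squares without lm() overhead; returns prediction at x0.
predict_linear <- function(x, y, x0) {
  n <- length(x)
  if (n < 2L) return(y[n])
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  if (vx <= 0) return(my)
  b <- sum((x - mx) * (y - my)) / vx
  my + b * (x0 - mx)
}

stop_domain <- function(...) stop(..., call. = FALSE)
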