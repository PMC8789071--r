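# Bell-Evans rupture kinetics under a constant loading rate: analytic
# density, (conditional) distribution function, quantile/sampler, and the
# most-probable rupture force.

.be_check <- function(k0, x_dagger, loading_rate, temperature) {
  vals <- c(k0 = k0, x_dagger = x_dagger, loading_rate = loading_rate,
            temperature = temperature)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad)) {
    stop_domain("Bell-Evans parameters must be positive: ",
                paste(names(vals)[bad], "=", vals[bad], collapse = ", "))
  }
}

#' Bell-Evans rupture-force density under a linear force ramp
#'
#' For escape rate \eqn{k(F) = k_0 e^{F x^\ddagger/kT}} and loading rate r,
#' the rupture-force density is
#' \deqn{p(F) = (k_0/r) e^{F x^\ddagger / kT}
#'   \exp\!\left[-\frac{k_0 kT}{r x^\ddagger}\left(e^{F x^\ddagger/kT} - 1\right)\right].}
#'
#' @param force Force in pN (>= 0).
#' @param k0 Zero-force escape rate, 1/s.
#' @param x_dagger Distance to the transition state, nm.
#' @param loading_rate Loading rate r, pN/s.
#' @param temperature Absolute temperature, K.
#' @return Density in 1/pN.
#' @export
bell_evans_pdf <- function(force, k0, x_dagger, loading_rate,
                           temperature = 296.15) {
  .be_check(k0, x_dagger, loading_rate, temperature)
  beta <- x_dagger / kT_pN_nm(temperature)    # 1/pN
  a <- k0 / (loading_rate * beta)
  (k0 / loading_rate) * exp(beta * force) * exp(-a * (exp(beta * force) - 1))
}

#' Bell-Evans rupture-force distribution function
#'
#' Optionally conditioned on survival to `f_min`, which matches a ramp whose
#' recording starts at `f_min`: `P(F <= f | F > f_min)`.
#'
#' @inheritParams bell_evans_pdf
#' @param f_min Conditioning force in pN (default 0, the unconditional CDF).
#' @return Probability in `[0, 1]`.
#' @export
bell_evans_cdf <- function(force, k0, x_dagger, loading_rate,
                           temperature = 296.15, f_min = 0) {
  .be_check(k0, x_dagger, loading_rate, temperature)
  beta <- x_dagger / kT_pN_nm(temperature)
  a <- k0 / (loading_rate * beta)
  surv <- function(f) exp(-a * (exp(beta * f) - 1))
  out <- 1 - surv(pmax(force, f_min)) / surv(f_min)
  pmin(pmax(out, 0), 1)
}

#' @rdname bell_evans_cdf
#' @param p Probability in `[0, 1)`.
#' @export
bell_evans_quantile <- function(p, k0, x_dagger, loading_rate,
                                temperature = 296.15, f_min = 0) {
  .be_check(k0, x_dagger, loading_rate, temperature)
  if (any(p < 0 | p >= 1)) stop_domain("p must be in [0, 1)")
  beta <- x_dagger / kT_pN_nm(temperature)
  a <- k0 / (loading_rate * beta)
  log(exp(beta * f_min) - log1p(-p) / a) / beta
}

#' Most probable Bell-Evans rupture force
#'
#' `F* = (kT/x_dagger) ln(r x_dagger / (k0 kT))`, valid when the log
#' argument exceeds 1 (otherwise the mode sits at zero force).
#'
#' @inheritParams bell_evans_pdf
#' @return Modal force in pN.
#' @export
bell_evans_mode <- function(k0, x_dagger, loading_rate, temperature = 296.15) {
  .be_check(k0, x_dagger, loading_rate, temperature)
  kT <- kT_pN_nm(temperature)
  max(0, (kT / x_dagger) * log(loading_rate * x_dagger / (k0 * kT)))
}

#' Zero-force rate that places the Bell-Evans mode at a target force
#'
#' Inverts [bell_evans_mode()]; used to build species tables from target
#' population centres.
#'
#' @param mode_force Desired most-probable rupture force, pN.
#' @inheritParams bell_evans_pdf
#' @return k0 in 1/s.
#' @export
bell_k0_for_mode <- function(mode_force, x_dagger, loading_rate,
                             temperature = 296.15) {
  stopifnot(mode_force > 0)
  beta <- x_dagger / kT_pN_nm(temperature)
  loading_rate * beta * exp(-beta * mode_force)
}

#' Sample rupture forces from the Bell-Evans distribution
#'
#' Inverse-CDF sampling, optionally conditional on survival to `f_min`.
#'
#' @param n Number of samples.
#' @inheritParams bell_evans_cdf
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return Numeric vector of rupture forces in pN.
#' @export
sample_bell_evans <- function(n, k0, x_dagger, loading_rate,
                              temperature = 296.15, f_min = 0, seed = NULL) {
  run_seeded(seed, function() {
    u <- stats::runif(n)
    bell_evans_quantile(u, k0, x_dagger, loading_rate, temperature, f_min)
  })
}
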