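# Worm-like-chain elasticity: Marko-Siggia interpolation, its numerical
# inverse, and the single-stranded-DNA model used for contour-length release.

#' Worm-like-chain force at a given relative extension
#'
#' Marko-Siggia interpolation formula
#' \deqn{F(z) = (kT/P)\,[1/(4(1-z)^2) - 1/4 + z]}
#' with `z` the end-to-end extension divided by contour length. When a
#' `stretch_modulus` K is supplied the extensible form is used: `z` is then
#' the total relative extension `x/L` and the force solves
#' `F = F_MS(z - F/K)` (enthalpic stretching added in series).
#'
#' @param relative_extension Relative extension. Inextensible form requires
#'   values in `[0, 1)`; the extensible form accepts any non-negative value
#'   for which a root with `z - F/K` in `[0, 1)` exists.
#' @param persistence_length Persistence length P in nm (> 0).
#' @param temperature Absolute temperature in K.
#' @param stretch_modulus Optional stretch modulus K in pN (> 0) for the
#'   extensible form.
#' @return Force in pN, same length as `relative_extension`. Strictly
#'   increasing in `relative_extension` and zero at zero extension.
#' @examples
#' wlc_force(0.5, persistence_length = 50, temperature = 296)
#' @export
wlc_force <- function(relative_extension, persistence_length = 50,
                      temperature = 296.15, stretch_modulus = NULL) {
  z <- relative_extension
  if (!is.numeric(z) || anyNA(z)) {
    stop_domain("relative_extension must be numeric and non-missing")
  }
  if (persistence_length <= 0) {
    stop_domain("persistence_length must be > 0 (got ", persistence_length, ")")
  }
  kT <- kT_pN_nm(temperature)
  if (is.null(stretch_modulus)) {
    bad <- z < 0 | z >= 1
    if (any(bad)) {
      stop_domain("relative extension out of [0, 1): ",
                  paste(signif(z[bad], 6), collapse = ", "))
    }
    return(.ms_force(z, persistence_length, kT))
  }
  K <- stretch_modulus
  if (K <= 0) stop_domain("stretch_modulus must be > 0 (got ", K, ")")
  if (any(z < 0)) {
    stop_domain("relative extension out of range: ",
                paste(signif(z[z < 0], 6), collapse = ", "))
  }
  vapply(z, function(zi) {
    if (zi == 0) return(0)
    # solve MS(w) - K (z - w) = 0 for the thermal part w = z - F/K
    fn <- function(w) .ms_force(w, persistence_length, kT) - K * (zi - w)
    stats::uniroot(fn, c(0, 1 - 1e-12), tol = 1e-12)$root -> w
    K * (zi - w)
  }, numeric(1))
}

# vectorised inextensible Marko-Siggia force
.ms_force <- function(z, P, kT) {
  (kT / P) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

# Monotone interpolator z(F) for the inextensible WLC; dense in z so the
# interpolation error in z stays below the grid pitch everywhere.
.wlc_z_of_force <- function(P, kT) {
  z <- seq(0, 0.999, by = 2.5e-5)
  f <- .ms_force(z, P, kT)
  function(force) stats::approx(f, z, xout = force, rule = 2)$y
}

#' Relative extension of a worm-like chain at a given force
#'
#' Numerical inverse of [wlc_force()]. With a `stretch_modulus` the
#' enthalpic term `F/K` is added, so the result is the total `x/L`.
#'
#' @inheritParams wlc_force
#' @param force Force in pN (>= 0).
#' @return Relative extension (dimensionless).
#' @export
wlc_extension <- function(force, persistence_length = 50,
                          temperature = 296.15, stretch_modulus = NULL) {
  if (any(force < 0)) {
    stop_domain("force must be >= 0: ",
                paste(signif(force[force < 0], 6), collapse = ", "))
  }
  kT <- kT_pN_nm(temperature)
  zf <- .wlc_z_of_force(persistence_length, kT)
  z <- zf(force)
  if (!is.null(stretch_modulus)) z <- z + force / stretch_modulus
  z
}

#' Single-stranded-DNA elasticity model
#'
#' Worm-like-chain description of the strand released when the
#' G-quadruplex unfolds, plus the end-to-end distance of the folded
#' structure, used for the expected contour-length release.
#'
#' @param contour_per_nt Contour length per nucleotide, nm/nt.
#' @param persistence_length ssDNA persistence length, nm.
#' @param folded_end_to_end End-to-end distance of the folded structure, nm.
#' @return An object of class `ssdna_model`.
#' @export
ssdna_model <- function(contour_per_nt = 0.44, persistence_length = 0.8,
                        folded_end_to_end = 2.0) {
  if (contour_per_nt <= 0 || persistence_length <= 0 || folded_end_to_end < 0) {
    stop_domain("ssdna_model parameters must be positive")
  }
  structure(list(contour_per_nt = contour_per_nt,
                 persistence_length = persistence_length,
                 folded_end_to_end = folded_end_to_end),
            class = "ssdna_model")
}

#' Fractional extension of single-stranded DNA at a force
#'
#' The extension per unit contour length of the released strand,
#' `phi_ss(F)`, from the inextensible WLC inverse at the ssDNA persistence
#' length. This is the factor that maps a contour-length release to an
#' extension jump at the rupture force.
#'
#' @param force Force in pN.
#' @param ss_model An [ssdna_model()].
#' @param temperature Absolute temperature in K.
#' @return Fractional extension in `[0, 1)`.
#' @export
ssdna_fractional_extension <- function(force, ss_model = ssdna_model(),
                                       temperature = 296.15) {
  stopifnot(inherits(ss_model, "ssdna_model"))
  wlc_extension(force, persistence_length = ss_model$persistence_length,
                temperature = temperature)
}
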