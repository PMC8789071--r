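# Physical constants used throughout. Forces are pN, lengths nm, energies
# kcal/mol unless a function says otherwise.

.kB_pN_nm <- 0.0138065     # Boltzmann constant, pN nm / K
.R_kcal <- 1.987e-3        # gas constant, kcal / (mol K)
.kcal_per_pN_nm <- 0.143932  # N_A * 1e-21 J / (4184 J/kcal)

#' Thermal energy in pN nm
#'
#' @param temperature Absolute temperature in K.
#' @return kT in pN nm.
#' @export
kT_pN_nm <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .kB_pN_nm * temperature
}

#' Thermal energy in kcal/mol
#'
#' @param temperature Absolute temperature in K.
#' @return RT in kcal/mol, with R = 1.987e-3 kcal/(mol K).
#' @export
RT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .R_kcal * temperature
}

#' Convert mechanical work between pN nm and kcal/mol
#'
#' 1 pN nm = 0.143932 kcal/mol (Avogadro scaling). The two functions are
#' exact inverses.
#'
#' @param x Numeric vector of work values.
#' @return Converted values.
#' @export
pN_nm_to_kcal <- function(x) x * .kcal_per_pN_nm

#' @rdname pN_nm_to_kcal
#' @export
kcal_to_pN_nm <- function(x) x / .kcal_per_pN_nm
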