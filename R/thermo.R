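# Free-energy machinery: the Jarzynski estimator with bias reporting, the
# thermodynamic (Hess-like) cycle for binding free energy, dissociation
# constants and affinity fold changes.

#' Construct a free-energy record
#'
#' @param value Free energy in kcal/mol.
#' @param bias Estimator bias in kcal/mol (see [jarzynski_dG()] for the
#'   conventions).
#' @param n_works Number of work values behind the estimate.
#' @param label State label (e.g. `"FreeGQ"`, `"GQ-PDS@NB"`).
#' @param temperature Absolute temperature, K.
#' @param method Bias method used, if any.
#' @return An object of class `free_energy`.
#' @export
free_energy <- function(value, bias = 0, n_works = NA_integer_,
                        label = NA_character_, temperature = 296.15,
                        method = NA_character_) {
  if (!is.finite(value) || !is.finite(bias)) {
    stop_domain("free energy value and bias must be finite")
  }
  structure(list(value = value, bias = bias,
                 n_works = as.integer(n_works), label = label,
                 temperature = temperature, method = method),
            class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("dG%s = %.2f (%+.2f) kcal/mol  [n = %s, T = %.2f K]\n",
              if (is.na(x$label)) "" else paste0("_", x$label),
              x$value, x$bias,
              if (is.na(x$n_works)) "?" else x$n_works, x$temperature))
  invisible(x)
}

.dg_value <- function(x) if (inherits(x, "free_energy")) x$value else as.numeric(x)
.dg_bias <- function(x) if (inherits(x, "free_energy")) x$bias else NA_real_

#' Jarzynski free-energy estimate from irreversible work values
#'
#' \deqn{\Delta G = -RT \ln \frac{1}{n}\sum_i e^{-W_i/RT}}
#' computed in log space (log-sum-exp) so large works never overflow. The
#' finite-sample estimator is biased; the bias is reported alongside the
#' point estimate:
#' * `bootstrap` (default): mean of the estimator over seeded bootstrap
#'   resamples minus the point estimate — positive when the estimator
#'   overshoots; degenerate (0) for a single work value.
#' * `gaussian_correction`: the additive large-n correction
#'   `-RT * var(e^{-W/RT}) / (2 n mean(e^{-W/RT})^2)` — negative for broad
#'   work distributions, i.e. the amount to add to de-bias the estimate.
#'
#' @param works Work values in kcal/mol (n >= 1, finite).
#' @param temperature Absolute temperature, K.
#' @param bias_method `"bootstrap"` or `"gaussian_correction"`.
#' @param seed Optional seed for the bootstrap.
#' @param n_bootstrap Bootstrap resamples (default 200).
#' @param label Optional state label carried into the result.
#' @return A [free_energy()] object.
#' @export
jarzynski_dG <- function(works, temperature = 296.15,
                         bias_method = c("bootstrap", "gaussian_correction"),
                         seed = NULL, n_bootstrap = 200,
                         label = NA_character_) {
  bias_method <- match.arg(bias_method)
  if (length(works) < 1) stop_domain("works must contain at least one value")
  bad <- which(!is.finite(works))
  if (length(bad)) {
    stop_domain("non-finite work values at indices: ",
                paste(bad, collapse = ", "))
  }
  rt <- RT_kcal(temperature)
  n <- length(works)
  s <- -works / rt
  point <- -rt * (logsumexp(s) - log(n))
  bias <- if (bias_method == "bootstrap") {
    if (n == 1L) 0 else run_seeded(seed, function() {
      est <- vapply(seq_len(n_bootstrap), function(b) {
        sb <- s[sample.int(n, n, replace = TRUE)]
        -rt * (logsumexp(sb) - log(n))
      }, numeric(1))
      mean(est) - point
    })
  } else {
    log_m1 <- logsumexp(s) - log(n)
    log_m2 <- logsumexp(2 * s) - log(n)
    ratio <- max(0, exp(log_m2 - 2 * log_m1) - 1)  # var/mean^2 in exp space
    -rt * ratio / (2 * n)
  }
  free_energy(point, bias, n_works = n, label = label,
              temperature = temperature, method = bias_method)
}

#' Binding free energy from a thermodynamic cycle
#'
#' The dissociation free energy of the bound complex equals the difference
#' of the unfolding free energies with and without the bound
#' ligand/cavity:
#' `dG(dissociation) = -dG(binding) = dG_unfold(complex) - dG_unfold(reference)`.
#'
#' @param dG_unfold_reference Unfolding free energy of the reference
#'   (unbound) state; a [free_energy()] or plain kcal/mol number.
#' @param dG_unfold_complex Unfolding free energy of the bound complex.
#' @return Dissociation free energy in kcal/mol, with the two estimator
#'   biases attached as attribute `biases`.
#' @examples
#' hess_cycle_dG(12, 27)  # 15 kcal/mol stabilisation
#' @export
hess_cycle_dG <- function(dG_unfold_reference, dG_unfold_complex) {
  if (inherits(dG_unfold_reference, "free_energy") &&
      inherits(dG_unfold_complex, "free_energy") &&
      !isTRUE(all.equal(dG_unfold_reference$temperature,
                        dG_unfold_complex$temperature))) {
    stop_domain("free energies were estimated at different temperatures")
  }
  out <- .dg_value(dG_unfold_complex) - .dg_value(dG_unfold_reference)
  attr(out, "biases") <- c(reference = .dg_bias(dG_unfold_reference),
                           complex = .dg_bias(dG_unfold_complex))
  out
}

#' Dissociation constant from a dissociation free energy
#'
#' `Kd = exp(-dG / (R T))` against the implicit 1 M standard state, with
#' R = 1.987e-3 kcal/(mol K). Strictly decreasing in `dG`.
#'
#' @param dG_dissociation Dissociation free energy, kcal/mol.
#' @param temperature Absolute temperature, K (> 0).
#' @return Kd in mol/L.
#' @examples
#' kd_from_dG(15, temperature = 298.15)  # ~1e-11 M, i.e. ~10 pM
#' @export
kd_from_dG <- function(dG_dissociation, temperature = 296.15) {
  if (any(temperature <= 0)) stop_domain("temperature must be > 0")
  exp(-.dg_value(dG_dissociation) / RT_kcal(temperature))
}

#' Apparent dissociation constant of a confining cavity
#'
#' Expresses the cavity's stabilisation of the folded structure as an
#' equivalent ligand affinity:
#' `Kd_apparent = exp(-(dG_unfold_confined - dG_unfold_free) / (R T))`.
#'
#' @param dG_unfold_confined Unfolding free energy inside the cavity,
#'   kcal/mol (or [free_energy()]).
#' @param dG_unfold_free Unfolding free energy of the free structure.
#' @param temperature Absolute temperature, K.
#' @return Apparent Kd in mol/L.
#' @export
apparent_kd <- function(dG_unfold_confined, dG_unfold_free,
                        temperature = 296.15) {
  kd_from_dG(.dg_value(dG_unfold_confined) - .dg_value(dG_unfold_free),
             temperature = temperature)
}

#' Affinity fold change between two dissociation constants
#'
#' @param kd_reference Reference Kd, mol/L (> 0).
#' @param kd_test Test Kd, mol/L (> 0).
#' @return A list with `fold = kd_reference / kd_test` and
#'   `orders = log10(fold)`.
#' @examples
#' affinity_fold_change(490e-9, 1e-11)  # ~49000-fold, 4.69 orders
#' @export
affinity_fold_change <- function(kd_reference, kd_test) {
  if (kd_reference <= 0 || kd_test <= 0) {
    stop_domain("dissociation constants must be > 0")
  }
  fold <- kd_reference / kd_test
  list(fold = fold, orders = log10(fold))
}

#' Assemble a thermodynamic summary
#'
#' Bundles per-state free energies with the cycle-derived dissociation
#' free energy, the dissociation constant (computed as
#' `exp(-dG/(R T))` by construction), the apparent cavity Kd, and the
#' fold change relative to a reference Kd.
#'
#' @param states Named list of [free_energy()] objects.
#' @param dG_dissociation Dissociation free energy, kcal/mol (or NULL).
#' @param kd_apparent Apparent Kd, mol/L (or NULL).
#' @param reference_kd Reference (dilute-solution) Kd, mol/L, for the fold
#'   change (or NULL).
#' @param temperature Absolute temperature, K.
#' @return An object of class `thermo_result`.
#' @export
thermo_result <- function(states = list(), dG_dissociation = NULL,
                          kd_apparent = NULL, reference_kd = NULL,
                          temperature = 296.15) {
  kd <- if (!is.null(dG_dissociation)) {
    kd_from_dG(dG_dissociation, temperature)
  }
  fc <- if (!is.null(kd) && !is.null(reference_kd)) {
    affinity_fold_change(reference_kd, kd)
  }
  structure(list(states = states,
                 dG_dissociation = if (is.null(dG_dissociation)) NULL else
                   .dg_value(dG_dissociation),
                 Kd = kd,
                 Kd_apparent = kd_apparent,
                 reference_kd = reference_kd,
                 fold_change = if (is.null(fc)) NULL else fc$fold,
                 orders_of_magnitude = if (is.null(fc)) NULL else fc$orders,
                 temperature = temperature,
                 gas_constant = .R_kcal),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("Thermodynamic summary (T =", x$temperature, "K)\n")
  for (s in x$states) print(s)
  if (!is.null(x$dG_dissociation)) {
    cat(sprintf("  dG_dissociation = %.2f kcal/mol -> Kd = %.3g M\n",
                x$dG_dissociation, x$Kd))
  }
  if (!is.null(x$Kd_apparent)) {
    cat(sprintf("  apparent cavity Kd = %.3g M\n", x$Kd_apparent))
  }
  if (!is.null(x$fold_change)) {
    cat(sprintf("  fold change vs reference (%.3g M): %.3g (%.2f orders)\n",
                x$reference_kd, x$fold_change, x$orders_of_magnitude))
  }
  invisible(x)
}
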