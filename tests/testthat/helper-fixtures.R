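# Shared fixtures, all generated in code.

# A constructed stretch-style trace: commanded load ramps linearly; each
# programmed rupture drops the measured force by `drop` pN and jumps the
# extension by `jump` nm.
fixture_trace <- function(ruptures = numeric(), drop = 3, f0 = 10, f1 = 30,
                          inc = 5.5e-3, noise_sd = 0, slope = 2.8,
                          jump = 6, direction = "stretch") {
  f_cmd <- seq(f0, f1, by = inc)
  off <- numeric(length(f_cmd))
  xoff <- numeric(length(f_cmd))
  for (fr in ruptures) {
    k <- f_cmd > fr
    off[k] <- off[k] + drop
    xoff[k] <- xoff[k] + jump
  }
  force <- f_cmd - off
  if (noise_sd > 0) force <- force + stats::rnorm(length(force), 0, noise_sd)
  forceramp:::.new_trace(
    trace_id = "fix_stretch", cycle_id = "fix", molecule_id = "molX",
    direction = direction, time = seq_along(f_cmd) / 1000,
    extension = 50 + slope * f_cmd + xoff, force = force)
}

# A bare fr_trace from explicit series (for work-integration geometry).
fixture_raw_trace <- function(extension, force, direction = "stretch",
                              id = "raw") {
  forceramp:::.new_trace(
    trace_id = id, cycle_id = "raw", molecule_id = "molX",
    direction = direction, time = seq_along(force) / 1000,
    extension = extension, force = force)
}

# A hand-built labelled-ready mixture object.
fixture_mixture <- function(means, weights = NULL, sds = 2) {
  k <- length(means)
  weights <- weights %||% rep(1 / k, k)
  sds <- rep_len(sds, k)
  structure(list(
    components = tibble::tibble(label = NA_character_, mean = means,
                                sd = sds, weight = weights / sum(weights)),
    n_events = 100L, n_molecules = NA_integer_, log_lik = 0,
    converged = TRUE, diagnostics = character(0)),
    class = "species_mixture")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# One 500-cycle experiment at the default study conditions, simulated and
# analysed once per test run and shared across files.
.fr_cache <- new.env(parent = emptyenv())
shared_experiment <- function() {
  if (is.null(.fr_cache$exp)) {
    .fr_cache$exp <- simulate_experiment(
      simulation_config(n_cycles = 500, seed = 42))
    .fr_cache$events <- analyze_experiment(.fr_cache$exp)
  }
  list(exp = .fr_cache$exp, events = .fr_cache$events)
}
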