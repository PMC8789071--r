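# Force-ramp pulling simulator: a dsDNA-handle tethered structure pulled at
# constant loading rate, with stochastic Bell-Evans unfolding that releases
# a fixed contour length of single-stranded DNA.

#' Build a species table for the simulator
#'
#' Each row is one unfolding species: a label, its mixture probability, the
#' Bell-Evans kinetics `(k0, x_dagger)` and the contour length `delta_L`
#' released on unfolding. `species_table()` derives `k0` from a target
#' most-probable rupture force via [bell_k0_for_mode()].
#'
#' @param label Character vector of species labels.
#' @param prob Mixture probabilities (sum to 1).
#' @param mode_force Target most-probable rupture force per species, pN.
#' @param x_dagger Transition-state distance per species, nm.
#' @param delta_L Contour length released per species, nm.
#' @param loading_rate,temperature Ramp conditions the modes refer to.
#' @return A tibble with columns label, prob, k0, x_dagger, delta_L.
#' @export
species_table <- function(label, prob, mode_force, x_dagger = 2.0,
                          delta_L = 8.0, loading_rate = 5.5,
                          temperature = 296.15) {
  n <- length(label)
  prob <- rep_len(prob, n); mode_force <- rep_len(mode_force, n)
  x_dagger <- rep_len(x_dagger, n); delta_L <- rep_len(delta_L, n)
  k0 <- mapply(bell_k0_for_mode, mode_force, x_dagger,
               MoreArgs = list(loading_rate = loading_rate,
                               temperature = temperature))
  tibble::tibble(label = label, prob = prob, k0 = k0,
                 x_dagger = x_dagger, delta_L = delta_L)
}

#' Default species table
#'
#' Three-species inventory of a nanocavity-tethered telomeric G-quadruplex
#' with a cavity-immobilized ligand: the free structure (mode 20 pN), the
#' cavity-confined structure (30 pN) and the ligand-bound confined complex
#' (47 pN), at mixture weights 0.48/0.26/0.26, each releasing 8 nm of
#' contour length on unfolding.
#'
#' @inheritParams species_table
#' @return A species tibble (see [species_table()]).
#' @export
default_species_table <- function(loading_rate = 5.5, temperature = 296.15) {
  species_table(label = c("FreeGQ", "GQ@NB", "GQ-PDS@NB"),
                prob = c(0.48, 0.26, 0.26),
                mode_force = c(20, 30, 47),
                x_dagger = 2.0, delta_L = 8.0,
                loading_rate = loading_rate, temperature = temperature)
}

.check_species_table <- function(st) {
  need <- c("label", "prob", "k0", "x_dagger", "delta_L")
  if (!is.data.frame(st) || nrow(st) == 0 || !all(need %in% names(st))) {
    stop_domain("species_table must be a non-empty data frame with columns ",
                paste(need, collapse = ", "))
  }
  if (any(st$prob < 0) || abs(sum(st$prob) - 1) > 1e-8) {
    stop_domain("species probabilities must be >= 0 and sum to 1")
  }
  if (any(st$k0 <= 0) || any(st$x_dagger <= 0) || any(st$delta_L < 0)) {
    stop_domain("species kinetics require k0 > 0, x_dagger > 0, delta_L >= 0")
  }
  invisible(st)
}

#' Simulation configuration
#'
#' Ground-truth parameters for [simulate_experiment()]. Defaults are the
#' experimental conditions of the emulated assay: two 2520-bp dsDNA handles
#' (0.34 nm/bp), persistence length 50 nm, stretch modulus 1200 pN, 23 C,
#' a ~5.5 pN/s ramp sampled at 1000 Hz, and white Gaussian force noise of
#' 0.5 pN. The ramp turnaround extends from 30 pN to 63 pN when the species
#' table contains high-force species.
#'
#' @param handle_contour_length Total handle contour length, nm.
#' @param persistence_length Handle persistence length, nm.
#' @param stretch_modulus Handle stretch modulus, pN.
#' @param temperature Absolute temperature, K.
#' @param loading_rate Ramp rate, pN/s.
#' @param sampling_rate Recording rate, Hz.
#' @param force_range Length-2 ramp turnaround forces, pN; `NULL` picks
#'   `c(10, 30)` or `c(10, 63)` depending on the species modes.
#' @param species_table Species inventory, see [species_table()].
#' @param noise_sd Gaussian force-noise standard deviation, pN.
#' @param n_cycles Number of stretch/relax cycles.
#' @param cycles_per_molecule Cycles attributed to one molecule (for the
#'   per-molecule count n).
#' @param refold_force Force below which the structure refolds on relax, pN.
#' @param seed Integer RNG seed.
#' @return An object of class `fr_sim_config`.
#' @export
simulation_config <- function(handle_contour_length = 0.34 * 5040,
                              persistence_length = 50,
                              stretch_modulus = 1200,
                              temperature = 296.15,
                              loading_rate = 5.5,
                              sampling_rate = 1000,
                              force_range = NULL,
                              species_table = NULL,
                              noise_sd = 0.5,
                              n_cycles = 100,
                              cycles_per_molecule = 25,
                              refold_force = 5,
                              seed = 1L) {
  pos <- c(handle_contour_length = handle_contour_length,
           persistence_length = persistence_length,
           stretch_modulus = stretch_modulus, temperature = temperature,
           loading_rate = loading_rate, sampling_rate = sampling_rate,
           n_cycles = n_cycles, cycles_per_molecule = cycles_per_molecule)
  bad <- !is.finite(pos) | pos <= 0
  if (any(bad)) {
    stop_domain("configuration fields must be positive: ",
                paste(names(pos)[bad], collapse = ", "))
  }
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (is.null(species_table)) {
    species_table <- default_species_table(loading_rate, temperature)
  }
  .check_species_table(species_table)
  modes <-mapply(bell_evans_mode, species_table$k0, species_table$x_dagger,
                  MoreArgs = list(loading_rate = loading_rate,
                                  temperature = temperature))
  if (is.null(force_range)) {
    force_range <- c(10, if (any(modes > 28)) 63 else 30)
  }
  if (length(force_range) != 2 || diff(force_range) <= 0 || force_range[1] <= 0) {
    stop_domain("force_range must be an increasing positive pair")
  }
  structure(list(handle_contour_length = handle_contour_length,
                 persistence_length = persistence_length,
                 stretch_modulus = stretch_modulus,
                 temperature = temperature,
                 loading_rate = loading_rate,
                 sampling_rate = sampling_rate,
                 force_range = force_range,
                 species_table = species_table,
                 noise_sd = noise_sd,
                 n_cycles = as.integer(n_cycles),
                 cycles_per_molecule = as.integer(cycles_per_molecule),
                 refold_force = refold_force,
                 seed = as.integer(seed)),
            class = "fr_sim_config")
}

#' @export
print.fr_sim_config <- function(x, ...) {
  cat("Force-ramp simulation config\n")
  cat(sprintf("  handle: L = %.1f nm, P = %.1f nm, K = %.0f pN\n",
              x$handle_contour_length, x$persistence_length, x$stretch_modulus))
  cat(sprintf("  ramp: %.2f pN/s over %.0f-%.0f pN at %.0f Hz, T = %.2f K\n",
              x$loading_rate, x$force_range[1], x$force_range[2],
              x$sampling_rate, x$temperature))
  cat(sprintf("  %d cycles (%d per molecule), noise sd %.2f pN, seed %d\n",
              x$n_cycles, x$cycles_per_molecule, x$noise_sd, x$seed))
  print(x$species_table)
  invisible(x)
}

.new_trace <- function(trace_id, cycle_id, molecule_id, direction,
                       time, extension, force, ground_truth = NULL) {
  structure(list(trace_id = trace_id, cycle_id = cycle_id,
                 molecule_id = molecule_id, direction = direction,
                 time = time, extension = extension, force = force,
                 ground_truth = ground_truth),
            class = "fr_trace")
}

#' @export
print.fr_trace <- function(x, ...) {
  cat(sprintf("<fr_trace %s | %s | %d samples | %.1f-%.1f pN>\n",
              x$trace_id, x$direction, length(x$force),
              min(x$force), max(x$force)))
  invisible(x)
}

#' Simulate a force-ramp pulling experiment
#'
#' For each cycle a species is drawn from the species table and a rupture
#' force from its Bell-Evans distribution (conditional on survival to the
#' ramp start). The commanded load ramps linearly; extension follows the
#' extensible-WLC handle. At rupture the tether extension is continuous, so
#' the force relaxes to the value at which the handle plus the released
#' single strand reproduce the pre-rupture extension, then the ramp resumes
#' -- producing the sawtooth force drop and the extension jump
#' `delta_L * phi_ss(F_rupture)` between the folded and unfolded branches.
#' The relax half-cycle follows the unfolded branch down to the refolding
#' force, giving hysteresis. Gaussian force noise is added to the recorded
#' force. Fully reproducible given the config seed.
#'
#' @param config An [simulation_config()] object.
#' @return An object of class `fr_experiment`: a list with `traces` (a list
#'   of `fr_trace` stretch/relax pairs), `ground_truth` (one row per cycle)
#'   and the `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "fr_sim_config"))
  st <- config$species_table
  kT <- kT_pN_nm(config$temperature)
  L <- config$handle_contour_length
  zf <- .wlc_z_of_force(config$persistence_length, kT)
  x_handle <- function(f) L * (zf(f) + f / config$stretch_modulus)
  zss <- .wlc_z_of_force(0.8, kT)  # replaced per-species below if needed
  phi_ss <- function(f) zss(f)
  inc <- config$loading_rate / config$sampling_rate
  fmin <- config$force_range[1]; fmax <- config$force_range[2]
  f_up <- seq(fmin, fmax, by = inc)
  n_up <- length(f_up)
  x_fold_up <- x_handle(f_up)
  f_down <- rev(f_up)

  run_seeded(config$seed, function() {
    sp_idx <- sample.int(nrow(st), config$n_cycles, replace = TRUE,
                         prob = st$prob)
    traces <- vector("list", 2L * config$n_cycles)
    gt <- vector("list", config$n_cycles)
    for (i in seq_len(config$n_cycles)) {
      sp <- st[sp_idx[i], ]
      fr <- sample_bell_evans(1, sp$k0, sp$x_dagger, config$loading_rate,
                              config$temperature, f_min = fmin)
      ruptured <- fr <= fmax
      molecule <- sprintf("mol%03d",
                          1L + (i - 1L) %/% config$cycles_per_molecule)
      cyc <- sprintf("cyc%04d", i)
      if (ruptured && sp$delta_L > 0) {
        j <- which(f_up >= fr)[1]                # first post-rupture sample
        # force after the jump: tether extension continuous at rupture
        target <- x_handle(fr)
        fprime <- stats::uniroot(function(f) {
          x_handle(f) + sp$delta_L * phi_ss(f) - target
        }, c(1e-3, fr), tol = 1e-9)$root
        f_post <- seq(fprime, fmax, by = inc)
        f_cmd <- c(f_up[seq_len(j - 1L)], f_post)
        x_s <- c(x_fold_up[seq_len(j - 1L)],
                 x_handle(f_post) + sp$delta_L * phi_ss(f_post))
        rupture_index <- j - 1L
      } else if (ruptured) {                     # delta_L = 0: silent event
        f_cmd <- f_up
        x_s <- x_fold_up
        rupture_index <- which(f_up >= fr)[1] - 1L
      } else {
        f_cmd <- f_up
        x_s <- x_fold_up
        rupture_index <- NA_integer_
      }
      n_s <- length(f_cmd)
      noise_s <- if (config$noise_sd > 0) {
        stats::rnorm(n_s, 0, config$noise_sd)
      } else 0
      gt_rec <- list(species = sp$label,
                     rupture_force = if (ruptured) fr else NA_real_,
                     delta_L = if (ruptured) sp$delta_L else NA_real_,
                     rupture_index = rupture_index)
      traces[[2L * i - 1L]] <- .new_trace(
        trace_id = paste0(cyc, "_stretch"), cycle_id = cyc,
        molecule_id = molecule, direction = "stretch",
        time = (seq_len(n_s) - 1L) / config$sampling_rate,
        extension = x_s, force = f_cmd + noise_s, ground_truth = gt_rec)
      # relax: unfolded branch above the refolding force if ruptured
      if (ruptured && sp$delta_L > 0) {
        unfolded <- f_down >= config$refold_force
        x_r <- x_handle(f_down) +
          ifelse(unfolded, sp$delta_L * phi_ss(f_down), 0)
      } else {
        x_r <- rev(x_fold_up)
      }
      n_r <- length(f_down)
      noise_r <- if (config$noise_sd > 0) {
        stats::rnorm(n_r, 0, config$noise_sd)
      } else 0
      traces[[2L * i]] <- .new_trace(
        trace_id = paste0(cyc, "_relax"), cycle_id = cyc,
        molecule_id = molecule, direction = "relax",
        time = (seq_len(n_r) - 1L) / config$sampling_rate,
        extension = x_r, force = f_down + noise_r, ground_truth = NULL)
      gt[[i]] <- tibble::tibble(
        cycle_id = cyc, trace_id = paste0(cyc, "_stretch"),
        molecule_id = molecule, species = sp$label,
        rupture_force = gt_rec$rupture_force,
        delta_L = gt_rec$delta_L,
        rupture_index = gt_rec$rupture_index)
    }
    structure(list(traces = traces,
                   ground_truth = do.call(rbind, gt),
                   config = config),
              class = "fr_experiment")
  })
}

#' @export
print.fr_experiment <- function(x, ...) {
  n_cyc <- nrow(x$ground_truth)
  cat(sprintf("<fr_experiment: %d cycles, %d traces>\n", n_cyc,
              length(x$traces)))
  print(table(x$ground_truth$species))
  invisible(x)
}

#' Flatten an experiment's traces to one table
#'
#' @param x An `fr_experiment`.
#' @param ... Unused.
#' @return A tibble with columns trace_id, cycle_id, molecule_id,
#'   direction, time_s, extension_nm, force_pN.
#' @export
as.data.frame.fr_experiment <- function(x, ...) {
  out <- lapply(x$traces, function(tr) {
    tibble::tibble(trace_id = tr$trace_id, cycle_id = tr$cycle_id,
                   molecule_id = tr$molecule_id, direction = tr$direction,
                   time_s = tr$time, extension_nm = tr$extension,
                   force_pN = tr$force)
  })
  as.data.frame(do.call(rbind, out))
}

#' Write / read a trace collection
#'
#' Traces go to a single tab-separated file with columns (trace_id,
#' cycle_id, direction, time_s, extension_nm, force_pN, molecule_id);
#' ground truth and the simulation config go to a JSON sidecar named
#' `<stem>_meta.json`.
#'
#' @param experiment An `fr_experiment`.
#' @param file Path of the TSV to write/read.
#' @return `write_traces()` returns the file path invisibly;
#'   `read_traces()` returns an `fr_experiment` (with `config` as a plain
#'   list and `ground_truth` when the sidecar is present).
#' @export
write_traces <- function(experiment, file) {
  stopifnot(inherits(experiment, "fr_experiment"))
  df <- as.data.frame(experiment)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(ground_truth = experiment$ground_truth,
               config = unclass(experiment$config))
  jsonlite::write_json(meta, .meta_path(file), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(file)
}

.meta_path <- function(file) {
  paste0(sub("\\.[A-Za-z]+$", "", file), "_meta.json")
}

#' @rdname write_traces
#' @export
read_traces <- function(file) {
  if (!file.exists(file)) stop_domain("trace file not found: ", file)
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  need <- c("trace_id", "cycle_id", "direction", "time_s", "extension_nm",
            "force_pN")
  if (!all(need %in% names(df))) {
    stop_domain("trace file must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(df$molecule_id)) df$molecule_id <- df$cycle_id
  ids <- unique(df$trace_id)
  traces <- lapply(ids, function(id) {
    d <- df[df$trace_id == id, ]
    .new_trace(trace_id = id, cycle_id = d$cycle_id[1],
               molecule_id = d$molecule_id[1], direction = d$direction[1],
               time = d$time_s, extension = d$extension_nm,
               force = d$force_pN)
  })
  gt <- NULL; cfg <- NULL
  mp <- .meta_path(file)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (!is.null(meta$ground_truth)) gt <- tibble::as_tibble(meta$ground_truth)
    cfg <- meta$config
  }
  structure(list(traces = traces, ground_truth = gt, config = cfg),
            class = "fr_experiment")
}
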