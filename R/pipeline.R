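# End-to-end orchestration: configuration with validation, the staged
# pipeline (simulate/load -> events -> deconvolution -> thermodynamics),
# report files and a checksummed manifest.

#' Default pipeline configuration
#'
#' Every stage parameter of the pipeline with its default. See
#' [validate_config()] for the schema rules and [run_pipeline()] for the
#' stages.
#'
#' @return A nested list of defaults (class `pipeline_config`).
#' @export
pipeline_defaults <- function() {
  structure(list(
    output_dir = NULL,
    input_traces = NULL,
    condition_label = "experiment",
    seed = 1L,
    temperature = 296.15,
    simulate = list(
      n_cycles = 100L, noise_sd = 0.5, loading_rate = 5.5,
      sampling_rate = 1000, handle_contour_length = 0.34 * 5040,
      persistence_length = 50, stretch_modulus = 1200,
      force_range = NULL, refold_force = 5, cycles_per_molecule = 25L,
      species_table = NULL),
    detect = list(min_drop = 1, window = 20L),
    delta_l = list(contour_per_nt = 0.44, persistence_length = 0.8,
                   folded_end_to_end = 2.0, branch_halfwidth = 2),
    work = list(force_window = NULL),
    deconvolve = list(k = NULL, context = "free_ligand", n_restarts = 10L),
    partition = list(window = c(32, 63), n_bootstrap = 200L,
                     method = "bootstrap"),
    thermo = list(bias_method = "bootstrap", n_bootstrap = 200L,
                  reference_label = "FreeGQ", complex_label = "GQ-PDS@NB",
                  confined_label = "GQ@NB", reference_kd = 490e-9,
                  min_works = 5L),
    plots = TRUE,
    log_level = "info"
  ), class = "pipeline_config")
}

# recursive merge of user values over defaults, collecting unknown keys
.merge_config <- function(defaults, user, path = character()) {
  unknown <- character()
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      valid <- names(defaults)
      d <- utils::adist(nm, valid)
      hint <- if (length(valid) && min(d) <= 3) {
        paste0(" (did you mean '", valid[which.min(d)], "'?)")
      } else ""
      unknown <- c(unknown, paste0(here, hint))
      next
    }
    if (is.list(defaults[[nm]]) && !is.data.frame(defaults[[nm]]) &&
        is.list(user[[nm]]) && !is.data.frame(user[[nm]])) {
      sub <- .merge_config(defaults[[nm]], user[[nm]], c(path, nm))
      defaults[[nm]] <- sub$config
      unknown <- c(unknown, sub$unknown)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  list(config = defaults, unknown = unknown)
}

#' Validate a pipeline configuration
#'
#' Accepts a (possibly partial) nested list, or a path to a YAML/JSON
#' file mirroring [pipeline_defaults()] field for field. Unknown keys are
#' rejected with their full dotted paths (and a nearest-key suggestion);
#' type and sign violations are all reported in one error. The returned
#' config is fully defaulted and round-trips losslessly through JSON.
#'
#' @param config A list, a `pipeline_config`, or a file path.
#' @return A complete `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_domain("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop_domain("config must be a list or file path")
  merged <- .merge_config(unclass(pipeline_defaults()), config)
  problems <- character()
  if (length(merged$unknown)) {
    problems <- c(problems,
                  paste0("unknown key: ", merged$unknown))
  }
  cfg <- merged$config
  check_pos <- function(value, name) {
    if (!is.null(value) && (!is.numeric(value) || anyNA(value) ||
                            any(value <= 0))) {
      problems <<- c(problems, paste0(name, " must be a positive number"))
    }
  }
  check_pos(cfg$temperature, "temperature")
  check_pos(cfg$simulate$loading_rate, "simulate.loading_rate")
  check_pos(cfg$simulate$sampling_rate, "simulate.sampling_rate")
  check_pos(cfg$simulate$n_cycles, "simulate.n_cycles")
  check_pos(cfg$simulate$handle_contour_length,
            "simulate.handle_contour_length")
  check_pos(cfg$simulate$persistence_length, "simulate.persistence_length")
  check_pos(cfg$simulate$stretch_modulus, "simulate.stretch_modulus")
  check_pos(cfg$detect$min_drop, "detect.min_drop")
  check_pos(cfg$detect$window, "detect.window")
  check_pos(cfg$delta_l$contour_per_nt, "delta_l.contour_per_nt")
  check_pos(cfg$delta_l$persistence_length, "delta_l.persistence_length")
  check_pos(cfg$partition$n_bootstrap, "partition.n_bootstrap")
  if (!is.null(cfg$simulate$noise_sd) &&
      (!is.numeric(cfg$simulate$noise_sd) || cfg$simulate$noise_sd < 0)) {
    problems <- c(problems, "simulate.noise_sd must be >= 0")
  }
  for (nm in c("simulate.force_range", "partition.window",
               "work.force_window")) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.null(v) && (length(v) != 2L || !is.numeric(v) || diff(v) <= 0)) {
      problems <- c(problems, paste0(nm, " must be an increasing pair"))
    }
  }
  if (!cfg$deconvolve$context %in% c("free_ligand", "immobilized_ligand")) {
    problems <- c(problems,
                  "deconvolve.context must be free_ligand or immobilized_ligand")
  }
  if (!cfg$partition$method %in% c("bootstrap", "stochastic")) {
    problems <- c(problems, "partition.method must be bootstrap or stochastic")
  }
  if (!cfg$thermo$bias_method %in% c("bootstrap", "gaussian_correction")) {
    problems <- c(problems,
                  "thermo.bias_method must be bootstrap or gaussian_correction")
  }
  if (length(problems)) {
    stop_domain("invalid configuration:\n  - ",
                paste(problems, collapse = "\n  - "))
  }
  # canonicalize count-like fields (YAML/JSON may deliver doubles)
  cfg$seed <- as.integer(cfg$seed)
  cfg$simulate$n_cycles <- as.integer(cfg$simulate$n_cycles)
  cfg$simulate$cycles_per_molecule <- as.integer(cfg$simulate$cycles_per_molecule)
  cfg$detect$window <- as.integer(cfg$detect$window)
  cfg$partition$n_bootstrap <- as.integer(cfg$partition$n_bootstrap)
  cfg$thermo$n_bootstrap <- as.integer(cfg$thermo$n_bootstrap)
  cfg$thermo$min_works <- as.integer(cfg$thermo$min_works)
  if (!is.null(cfg$deconvolve$k)) cfg$deconvolve$k <- as.integer(cfg$deconvolve$k)
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[forceramp] %s", paste0(...)))
}

.write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  path
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load traces from `input_traces` or simulate them with the
#' configured generator; (2) detect ruptures and measure delta_L and
#' hysteresis work; (3) deconvolve the rupture-force histogram into
#' labelled species populations and, when enough high-force events exist,
#' partition them into proximity/confinement components; (4) estimate
#' per-species Jarzynski free energies and, when the reference and
#' complex species are both present, the cycle dissociation free energy,
#' Kd, apparent cavity Kd and fold change. Writes `events.csv`,
#' `populations.json`, `population_table.csv`/`.md`, `thermo.json`, a
#' rupture-force histogram PNG, and `manifest.json` with the config hash
#' and per-file checksums. Identical config + seed give byte-identical
#' JSON reports; a stage failure aborts with a stage-named error and
#' leaves a `FAILED` marker next to any partial outputs.
#'
#' @param config Anything accepted by [validate_config()]; must contain
#'   `output_dir`.
#' @return Invisibly, a list with the events table, the labelled mixture,
#'   the partition, the `thermo_result` and the output paths.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  if (is.null(cfg$output_dir)) stop_domain("config must set output_dir")
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 failed_marker)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  experiment <- stage("load_or_simulate", function() {
    if (!is.null(cfg$input_traces)) {
      .log_stage(cfg, "loading traces from ", cfg$input_traces)
      read_traces(cfg$input_traces)
    } else {
      .log_stage(cfg, "simulating ", cfg$simulate$n_cycles,
                 " cycles (seed ", cfg$seed, ")")
      sim <- cfg$simulate
      simulate_experiment(simulation_config(
        handle_contour_length = sim$handle_contour_length,
        persistence_length = sim$persistence_length,
        stretch_modulus = sim$stretch_modulus,
        temperature = cfg$temperature,
        loading_rate = sim$loading_rate,
        sampling_rate = sim$sampling_rate,
        force_range = sim$force_range,
        species_table = sim$species_table,
        noise_sd = sim$noise_sd,
        n_cycles = sim$n_cycles,
        cycles_per_molecule = sim$cycles_per_molecule,
        refold_force = sim$refold_force,
        seed = cfg$seed))
    }
  })

  ssm <- ssdna_model(cfg$delta_l$contour_per_nt,
                     cfg$delta_l$persistence_length,
                     cfg$delta_l$folded_end_to_end)
  events <- stage("trace_analysis", function() {
    .log_stage(cfg, "extracting rupture events")
    ev <- analyze_experiment(experiment,
                             min_drop = cfg$detect$min_drop,
                             window = cfg$detect$window,
                             ss_model = ssm,
                             force_window = cfg$work$force_window,
                             branch_halfwidth = cfg$delta_l$branch_halfwidth,
                             temperature = cfg$temperature)
    if (nrow(ev) == 0) stop("no rupture events detected", call. = FALSE)
    ev
  })
  events_path <- file.path(out, "events.csv")
  utils::write.csv(events, events_path, row.names = FALSE)

  deconv <- stage("deconvolution", function() {
    forces <- events$rupture_force_pN[is.finite(events$rupture_force_pN)]
    k <- cfg$deconvolve$k
    if (is.null(k)) {
      k <- if (!is.null(experiment$config) &&
               !is.null(experiment$config$species_table)) {
        nrow(experiment$config$species_table)
      } else {
        stop("deconvolve.k must be set when analysing external traces",
             call. = FALSE)
      }
    }
    .log_stage(cfg, "fitting ", k, "-component mixture to ",
               length(forces), " rupture forces")
    n_mol <- length(unique(events$molecule_id))
    mix <- fit_mixture(forces, k, seed = cfg$seed + 1L,
                       n_restarts = cfg$deconvolve$n_restarts,
                       n_molecules = n_mol)
    mix <- assign_species(mix, context = cfg$deconvolve$context)
    part <- NULL
    n_in <- sum(forces >= cfg$partition$window[1] &
                  forces <= cfg$partition$window[2])
    if (n_in >= 30) {
      part <- partition_effects(forces, window = cfg$partition$window,
                                seed = cfg$seed + 2L,
                                n_bootstrap = cfg$partition$n_bootstrap,
                                method = cfg$partition$method)
    }
    list(mixture = mix, partition = part, forces = forces)
  })
  mixtures <- stats::setNames(list(deconv$mixture), cfg$condition_label)
  pop_tbl <- population_table(mixtures)
  utils::write.csv(pop_tbl, file.path(out, "population_table.csv"),
                   row.names = FALSE)
  writeLines(format_population_table(pop_tbl),
             file.path(out, "population_table.md"))
  pop_json <- list(
    condition = cfg$condition_label,
    n_events = deconv$mixture$n_events,
    n_molecules = deconv$mixture$n_molecules,
    components = deconv$mixture$components,
    log_lik = deconv$mixture$log_lik,
    converged = deconv$mixture$converged,
    diagnostics = deconv$mixture$diagnostics,
    partition = if (!is.null(deconv$partition)) list(
      proximity_fraction = deconv$partition$proximity_fraction,
      confinement_fraction = deconv$partition$confinement_fraction,
      component_means = deconv$partition$components$mean,
      ci = as.data.frame(deconv$partition$ci),
      degenerate = deconv$partition$degenerate,
      n_in_window = deconv$partition$n_in_window,
      method = deconv$partition$method))
  .write_report_json(pop_json, file.path(out, "populations.json"))

  thermo <- stage("thermodynamics", function() {
    lab <- classify_events(deconv$mixture, events$rupture_force_pN)
    works <- split(events$work_kcal_mol, lab)
    works <- lapply(works, function(w) w[is.finite(w)])
    works <- works[vapply(works, length, 1L) >= cfg$thermo$min_works]
    .log_stage(cfg, "Jarzynski estimates for: ",
               paste(names(works), collapse = ", "))
    states <- list()
    for (i in seq_along(works)) {
      states[[names(works)[i]]] <- jarzynski_dG(
        works[[i]], temperature = cfg$temperature,
        bias_method = cfg$thermo$bias_method,
        seed = cfg$seed + 10L + i, n_bootstrap = cfg$thermo$n_bootstrap,
        label = names(works)[i])
    }
    ref <- states[[cfg$thermo$reference_label]]
    cpx <- states[[cfg$thermo$complex_label]]
    cnf <- states[[cfg$thermo$confined_label]]
    dg_diss <- if (!is.null(ref) && !is.null(cpx)) hess_cycle_dG(ref, cpx)
    kda <- if (!is.null(ref) && !is.null(cnf)) {
      apparent_kd(cnf, ref, temperature = cfg$temperature)
    }
    thermo_result(states = states, dG_dissociation = dg_diss,
                  kd_apparent = kda,
                  reference_kd = cfg$thermo$reference_kd,
                  temperature = cfg$temperature)
  })
  thermo_json <- list(
    temperature_K = thermo$temperature,
    gas_constant_kcal_mol_K = thermo$gas_constant,
    states = lapply(thermo$states, function(s) {
      list(value_kcal_mol = s$value, bias_kcal_mol = s$bias,
           n_works = s$n_works, method = s$method)
    }),
    dG_dissociation_kcal_mol = thermo$dG_dissociation,
    Kd_M = thermo$Kd,
    Kd_apparent_M = thermo$Kd_apparent,
    reference_kd_M = thermo$reference_kd,
    fold_change = thermo$fold_change,
    orders_of_magnitude = thermo$orders_of_magnitude)
  .write_report_json(thermo_json, file.path(out, "thermo.json"))

  stage("plots", function() {
    if (!isTRUE(cfg$plots)) return(invisible())
    tryCatch({
      path <- file.path(out, "rupture_histogram.png")
      grDevices::png(path, width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      f <- deconv$forces
      breaks <- seq(2 * floor(min(f) / 2), 2 * ceiling(max(f) / 2), by = 2)
      graphics::hist(f, breaks = breaks, freq = FALSE,
                     col = "grey85", border = "white",
                     xlab = "Rupture force (pN)",
                     main = "Rupture-force populations")
      xx <- seq(min(f) - 2, max(f) + 2, length.out = 400)
      comp <- deconv$mixture$components
      for (j in seq_len(nrow(comp))) {
        graphics::lines(xx, comp$weight[j] *
                          stats::dnorm(xx, comp$mean[j], comp$sd[j]),
                        lwd = 2, col = j + 1)
      }
      graphics::legend("topright", legend = sprintf(
        "%s: %.1f pN (%.0f%%)", comp$label, comp$mean, 100 * comp$weight),
        col = seq_len(nrow(comp)) + 1, lwd = 2, bty = "n")
    }, error = function(e) {
      .log_stage(cfg, "plotting skipped: ", conditionMessage(e))
    })
  })

  # manifest with a canonical config hash and per-file checksums
  cfg_path <- file.path(out, "config.json")
  .write_report_json(unclass(cfg), cfg_path)
  files <- c("events.csv", "populations.json", "population_table.csv",
             "population_table.md", "thermo.json", "config.json")
  files <- files[file.exists(file.path(out, files))]
  manifest <- list(
    package = "forceramp",
    version = as.character(utils::packageVersion("forceramp")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    outputs = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out, f)))
    }))
  .write_report_json(manifest, file.path(out, "manifest.json"))
  .log_stage(cfg, "report written to ", out)

  invisible(list(events = events, mixture = deconv$mixture,
                 partition = deconv$partition,
                 population_table = pop_tbl, thermo = thermo,
                 output_dir = out,
                 files = file.path(out, c(files, "manifest.json"))))
}
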