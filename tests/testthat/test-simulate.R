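test_that("identical config and seed give bit-identical experiments", {
  cfg <- simulation_config(n_cycles = 5, seed = 7)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$traces, b$traces)
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- simulate_experiment(simulation_config(n_cycles = 5, seed = 8))
  expect_false(identical(a$ground_truth$rupture_force,
                         c_$ground_truth$rupture_force))
})

test_that("trace series are well-formed", {
  ex <- simulate_experiment(simulation_config(n_cycles = 3, seed = 1))
  for (tr in ex$traces) {
    expect_true(all(diff(tr$time) > 0))
    expect_gte(length(tr$force), 2L)
    expect_identical(length(tr$force), length(tr$extension))
    expect_identical(length(tr$force), length(tr$time))
  }
})

test_that("a transition-free species gives no hysteresis and zero work", {
  st <- species_table("none", 1, mode_force = 20, delta_L = 0)
  cfg <- simulation_config(n_cycles = 2, seed = 3, noise_sd = 0,
                           species_table = st)
  ex <- simulate_experiment(cfg)
  s <- ex$traces[[1]]; r <- ex$traces[[2]]
  expect_equal(s$extension, rev(r$extension), tolerance = 1e-12)
  expect_equal(s$force, rev(r$force), tolerance = 1e-12)
  expect_equal(compute_work(s, r, force_window = c(10, 30)), 0,
               tolerance = 1e-9)
})

test_that("every cycle has exactly one ground-truth record and species counts are multinomial", {
  ex <- simulate_experiment(simulation_config(n_cycles = 200, seed = 5))
  expect_identical(nrow(ex$ground_truth), 200L)
  expect_identical(anyDuplicated(ex$ground_truth$cycle_id), 0L)
  obs <- table(factor(ex$ground_truth$species,
                      levels = c("FreeGQ", "GQ@NB", "GQ-PDS@NB")))
  gof <- stats::chisq.test(obs, p = c(0.48, 0.26, 0.26))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulated rupture forces follow the Bell-Evans law", {
  st <- species_table("one", 1, mode_force = 20)
  cfg <- simulation_config(n_cycles = 1000, seed = 9, species_table = st,
                           sampling_rate = 200, force_range = c(10, 30))
  ex <- simulate_experiment(cfg)
  fr <- ex$ground_truth$rupture_force
  fr <- fr[is.finite(fr)]
  expect_gte(length(fr), 990)
  ks <- suppressWarnings(stats::ks.test(
    fr, function(q) bell_evans_cdf(q, st$k0, st$x_dagger, 5.5, 296.15,
                                   f_min = 10)))
  expect_gt(ks$p.value, 0.01)
})

test_that("trace tables round-trip through the TSV + sidecar format", {
  ex <- simulate_experiment(simulation_config(n_cycles = 3, seed = 2))
  tmp <- file.path(withr::local_tempdir(), "traces.tsv")
  write_traces(ex, tmp)
  back <- read_traces(tmp)
  expect_identical(length(back$traces), length(ex$traces))
  expect_equal(back$traces[[1]]$force, ex$traces[[1]]$force,
               tolerance = 1e-9)
  expect_equal(back$traces[[1]]$extension, ex$traces[[1]]$extension,
               tolerance = 1e-9)
  expect_identical(back$ground_truth$species, ex$ground_truth$species)
  expect_error(read_traces(file.path(tempdir(), "missing.tsv")),
               "not found")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(loading_rate = -1), "loading_rate")
  expect_error(simulation_config(
    species_table = data.frame(label = "a", prob = 0.5, k0 = 1,
                               x_dagger = 1, delta_L = 8)), "sum to 1")
  expect_error(simulation_config(species_table = data.frame()), "non-empty")
})
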