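test_that("a programmed rupture is found at its force; featureless traces give none", {
  tr <- fixture_trace(ruptures = 25)
  ev <- detect_ruptures(tr)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$rupture_force, 25, tolerance = 0.02)
  expect_identical(nrow(detect_ruptures(fixture_trace())), 0L)
})

test_that("two programmed ruptures are returned in time order", {
  tr <- fixture_trace(ruptures = c(18, 25))
  ev <- detect_ruptures(tr)
  expect_identical(nrow(ev), 2L)
  expect_true(all(diff(ev$rupture_index) > 0))
  expect_equal(ev$rupture_force, c(18, 25 - 3), tolerance = 0.02)
})

test_that("relax-direction and degenerate traces are usage errors", {
  expect_error(detect_ruptures(fixture_trace(direction = "relax")),
               "stretch")
  short <- fixture_raw_trace(1:3, c(10, 11, 12))
  expect_error(detect_ruptures(short), "window")
})

test_that("noise-free simulations are detected completely with no false positives", {
  ex <- simulate_experiment(simulation_config(n_cycles = 40, seed = 3,
                                              noise_sd = 0))
  gt <- ex$ground_truth
  resolvable <- gt[!is.na(gt$rupture_index) & gt$rupture_index >= 20, ]
  ev <- analyze_experiment(ex)
  expect_identical(nrow(ev), nrow(resolvable))
  m <- match(ev$cycle_id, resolvable$cycle_id)
  expect_false(anyNA(m))
  expect_true(all(abs(ev$rupture_index - resolvable$rupture_index[m]) <= 2))
  expect_true(all(abs(ev$rupture_force_pN -
                        resolvable$rupture_force[m]) < 0.05))
})

test_that("contour-length release is recovered exactly without noise", {
  ex <- simulate_experiment(simulation_config(n_cycles = 20, seed = 13,
                                              noise_sd = 0))
  ev <- analyze_experiment(ex)
  expect_true(all(abs(ev$delta_L_nm - 8) < 0.2))
})

test_that("contour-length release is recovered at realistic noise", {
  sh <- shared_experiment()
  dl <- sh$events$delta_L_nm
  dl <- dl[is.finite(dl)]
  expect_gte(length(dl), 400)
  expect_lt(abs(mean(dl) - 8), 0.5)
  # median absolute error within 5% of the 8 nm truth
  expect_lte(stats::median(abs(dl - 8)), 0.4)
})

test_that("expected contour-length release follows the ssDNA arithmetic", {
  expect_equal(expected_delta_L(21), 21 * 0.44 - 2.0, tolerance = 1e-12)
  expect_equal(expected_delta_L(21), 7.24, tolerance = 1e-9)
  expect_equal(expected_delta_L(1, ssdna_model(folded_end_to_end = 0)),
               0.44, tolerance = 1e-12)
  expect_error(expected_delta_L(0), "n_nt")
})

test_that("hysteresis work reproduces constructed geometry and the reversible limit", {
  # rectangle: 2 pN force gap over 10 nm -> 20 pN nm
  xs <- seq(0, 10, by = 0.1)
  s <- fixture_raw_trace(xs, rep(12, length(xs)))
  r <- fixture_raw_trace(rev(xs), rep(10, length(xs)), direction = "relax")
  w <- compute_work(s, r, force_window = c(9, 13))
  expect_equal(w, pN_nm_to_kcal(20), tolerance = 1e-9)
  expect_equal(w, 2.88, tolerance = 0.01)
  # stretch == relax -> zero work
  r2 <- fixture_raw_trace(rev(xs), rep(12, length(xs)), direction = "relax")
  expect_equal(compute_work(s, r2, force_window = c(9, 13)), 0,
               tolerance = 1e-12)
  # disjoint extension ranges are a domain error
  r3 <- fixture_raw_trace(rev(xs) + 100, rep(10, length(xs)),
                          direction = "relax")
  expect_error(compute_work(s, r3, force_window = c(9, 13)), "overlap")
})

test_that("simulated irreversible cycles dissipate positive work", {
  sh <- shared_experiment()
  w <- sh$events$work_kcal_mol
  w <- w[is.finite(w)]
  expect_gt(length(w), 400)
  expect_true(all(w > -0.5))
  expect_gt(mean(w), 1)
})

test_that("energy unit conversion round-trips exactly", {
  x <- c(0.1, 1, 20, 250)
  expect_equal(kcal_to_pN_nm(pN_nm_to_kcal(x)), x, tolerance = 1e-12)
  expect_equal(pN_nm_to_kcal(1), 0.1439, tolerance = 1e-3)
})
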