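rt <- RT_kcal(296.15)

test_that("degenerate work samples return the work itself with zero bias", {
  one <- jarzynski_dG(17.3, seed = 1)
  expect_equal(one$value, 17.3, tolerance = 1e-12)
  expect_identical(one$bias, 0)
  same <- jarzynski_dG(rep(9.2, 50), seed = 1)
  expect_equal(same$value, 9.2, tolerance = 1e-12)
  expect_equal(same$bias, 0, tolerance = 1e-9)
})

test_that("bad work inputs are rejected naming the offenders", {
  expect_error(jarzynski_dG(numeric(0)), "at least one")
  expect_error(jarzynski_dG(c(1, NA, 3, Inf)), "2, 4")
})

test_that("the estimator converges to the Gaussian closed form", {
  # works ~ N(mu, sigma) => dG -> mu - sigma^2 / (2 RT)
  mu <- 20; sigma <- 2
  truth <- mu - sigma^2 / (2 * rt)
  expect_equal(truth, 16.60, tolerance = 0.005)
  errs <- withr::with_seed(21, vapply(c(100, 1000, 10000), function(n) {
    mean(vapply(1:5, function(r) {
      abs(jarzynski_dG(stats::rnorm(n, mu, sigma), 296.15,
                       bias_method = "gaussian_correction")$value - truth)
    }, numeric(1)))
  }, numeric(1)))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.2)
})

test_that("the estimate never exceeds the mean work (second law / Jensen)", {
  withr::with_seed(31, {
    for (i in 1:20) {
      w <- stats::rnorm(50, stats::runif(1, 5, 30), stats::runif(1, 0.1, 4))
      dg <- jarzynski_dG(w, 296.15, bias_method = "gaussian_correction")
      expect_lte(dg$value, mean(w) + 1e-9)
      if (stats::sd(w) > 0.2) expect_lt(dg$value, mean(w))
    }
  })
})

test_that("the analytic bias correction is negative for broad work distributions", {
  w <- withr::with_seed(41, stats::rnorm(500, 15, 2.5))
  dg <- jarzynski_dG(w, 296.15, bias_method = "gaussian_correction")
  expect_lt(dg$bias, 0)
  dgb <- jarzynski_dG(w, 296.15, bias_method = "bootstrap", seed = 5)
  expect_true(is.finite(dgb$bias))
})

test_that("the thermodynamic cycle subtracts unfolding free energies", {
  dg <- hess_cycle_dG(12, 27)
  expect_equal(as.numeric(dg), 15, tolerance = 1e-12)
  expect_equal(as.numeric(hess_cycle_dG(8.1, 8.1)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(hess_cycle_dG(27, 12)), -15, tolerance = 1e-12)
  ref <- free_energy(12, -0.8, 100, "GQ")
  cpx <- free_energy(27, 1.3, 80, "GQ-PDS@NB")
  dg2 <- hess_cycle_dG(ref, cpx)
  expect_equal(unname(attr(dg2, "biases")), c(-0.8, 1.3))
  expect_error(hess_cycle_dG(ref, free_energy(27, temperature = 310)),
               "temperature")
})

test_that("Kd conversion is exact, monotone, and round-trips", {
  expect_equal(kd_from_dG(0, 296.15), 1, tolerance = 1e-12)
  expect_equal(kd_from_dG(rt * log(10), 296.15), 0.1, tolerance = 1e-12)
  for (K in c(1e-3, 1e-7, 1e-11)) {
    expect_equal(kd_from_dG(-rt * log(K), 296.15), K, tolerance = 1e-12)
  }
  dg <- c(5, 10, 15)
  expect_true(all(diff(kd_from_dG(dg, 296.15)) < 0))
  expect_error(kd_from_dG(10, temperature = -1), "temperature")
})

test_that("the cavity's apparent Kd follows from the confinement stabilization", {
  expect_equal(apparent_kd(20.47, 12), 5.61e-7, tolerance = 0.01)
  expect_equal(apparent_kd(12, 12), 1, tolerance = 1e-12)
  # stronger confinement stabilization => tighter apparent Kd
  expect_lt(apparent_kd(22, 12), apparent_kd(20, 12))
})

test_that("affinity fold changes and orders of magnitude are consistent", {
  fc <- affinity_fold_change(490e-9, 1e-11)
  expect_equal(fc$fold, 49000, tolerance = 1e-12)
  expect_equal(fc$orders, 4.69, tolerance = 0.001)
  expect_identical(affinity_fold_change(2e-9, 2e-9)$fold, 1)
  expect_identical(affinity_fold_change(1e-6, 1e-9)$orders, 3)
  expect_error(affinity_fold_change(-1, 1e-9), "positive|> 0")
})

test_that("thermo_result enforces Kd = exp(-dG/RT) by construction", {
  tr <- thermo_result(dG_dissociation = 15, reference_kd = 490e-9,
                      temperature = 296.15)
  expect_equal(tr$Kd, exp(-15 / rt), tolerance = 1e-15)
  expect_equal(tr$fold_change, 490e-9 / tr$Kd, tolerance = 1e-12)
})
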