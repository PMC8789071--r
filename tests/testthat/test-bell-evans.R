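kT <- kT_pN_nm(296.15)

test_that("rupture-force density normalizes and matches its distribution function", {
  k0 <- bell_k0_for_mode(20, 2, 5.5, 296.15)
  expect_equal(
    stats::integrate(function(f) bell_evans_pdf(f, k0, 2, 5.5, 296.15),
                     0, 200)$value, 1, tolerance = 1e-6)
  # CDF is the integral of the pdf
  for (q in c(10, 18, 25)) {
    expect_equal(
      bell_evans_cdf(q, k0, 2, 5.5, 296.15),
      stats::integrate(function(f) bell_evans_pdf(f, k0, 2, 5.5, 296.15),
                       0, q)$value,
      tolerance = 1e-6)
  }
})

test_that("density mode agrees with the closed form", {
  k0 <- bell_k0_for_mode(20, 2, 5.5, 296.15)
  grid <- seq(0, 40, by = 0.01)
  argmax <- grid[which.max(bell_evans_pdf(grid, k0, 2, 5.5, 296.15))]
  expect_equal(argmax, bell_evans_mode(k0, 2, 5.5, 296.15), tolerance = 0.011)
  expect_equal(bell_evans_mode(k0, 2, 5.5, 296.15), 20, tolerance = 1e-9)
})

test_that("doubling the loading rate shifts the mode by kT/x * ln 2", {
  k0 <- bell_k0_for_mode(25, 1.5, 5.5, 296.15)
  shift <- bell_evans_mode(k0, 1.5, 11, 296.15) -
    bell_evans_mode(k0, 1.5, 5.5, 296.15)
  expect_equal(shift, (kT / 1.5) * log(2), tolerance = 1e-10)
})

test_that("quantile inverts the (conditional) distribution function", {
  k0 <- bell_k0_for_mode(20, 2, 5.5, 296.15)
  p <- c(0.01, 0.25, 0.5, 0.9, 0.999)
  for (fmin in c(0, 10)) {
    q <- bell_evans_quantile(p, k0, 2, 5.5, 296.15, f_min = fmin)
    expect_equal(bell_evans_cdf(q, k0, 2, 5.5, 296.15, f_min = fmin), p,
                 tolerance = 1e-10)
  }
})

test_that("inverse-CDF samples pass a KS test against the analytic law", {
  k0 <- bell_k0_for_mode(20, 2, 5.5, 296.15)
  x <- sample_bell_evans(2000, k0, 2, 5.5, 296.15, f_min = 10, seed = 11)
  ks <- suppressWarnings(stats::ks.test(
    x, function(q) bell_evans_cdf(q, k0, 2, 5.5, 296.15, f_min = 10)))
  expect_gt(ks$p.value, 0.01)
})

test_that("non-positive kinetic parameters are rejected", {
  expect_error(bell_evans_pdf(10, -1, 2, 5.5), "k0")
  expect_error(bell_evans_pdf(10, 1e-4, 0, 5.5), "x_dagger")
  expect_error(bell_evans_mode(1e-4, 2, -5.5), "loading_rate")
})
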