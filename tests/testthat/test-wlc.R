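test_that("Marko-Siggia force matches the closed form and its limits", {
  expect_identical(wlc_force(0, 50, 296), 0)
  # z = 0.5: bracket term is 1.25, so F = 1.25 kT/P
  kT <- kT_pN_nm(296)
  expect_equal(wlc_force(0.5, 50, 296), 1.25 * kT / 50, tolerance = 1e-10)
  expect_equal(wlc_force(0.5, 50, 296), 0.102, tolerance = 1e-2)
})

test_that("WLC force is strictly increasing and diverges toward full extension", {
  z <- seq(0, 0.99, by = 0.01)
  f <- wlc_force(z, 50, 296.15)
  expect_true(all(diff(f) > 0))
  expect_gt(wlc_force(0.999, 50, 296.15), wlc_force(0.99, 50, 296.15) * 10)
})

test_that("out-of-range extensions are rejected naming the offending value", {
  expect_error(wlc_force(1.2, 50, 296.15), "1.2")
  expect_error(wlc_force(-0.1, 50, 296.15), "-0.1")
  expect_error(wlc_force(0.5, -5, 296.15), "persistence")
})

test_that("extensible WLC adds enthalpic compliance and inverts consistently", {
  # at the same total relative extension the extensible chain carries less
  # force, part of the extension being backbone stretch
  expect_lt(wlc_force(0.9, 50, 296.15, stretch_modulus = 1200),
            wlc_force(0.9, 50, 296.15))
  for (f in c(2, 10, 30, 50)) {
    z <- wlc_extension(f, 50, 296.15, stretch_modulus = 1200)
    expect_equal(wlc_force(z, 50, 296.15, stretch_modulus = 1200), f,
                 tolerance = 1e-3)
    z0 <- wlc_extension(f, 50, 296.15)
    expect_equal(wlc_force(z0, 50, 296.15), f, tolerance = 1e-3)
  }
})

test_that("ssDNA fractional extension is a proper fraction, increasing in force", {
  f <- c(5, 15, 25, 47)
  phi <- ssdna_fractional_extension(f)
  expect_true(all(phi > 0 & phi < 1))
  expect_true(all(diff(phi) > 0))
})
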