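test_that("a single Gaussian population is recovered with weight one", {
  x <- withr::with_seed(1, stats::rnorm(1000, 30, 3))
  m <- fit_mixture(x, 1)
  expect_equal(m$components$mean, 30, tolerance = 0.3)
  expect_equal(m$components$sd, 3, tolerance = 0.3)
  expect_identical(m$components$weight, 1)
  expect_true(m$converged)
})

test_that("well-separated equal mixtures are recovered and sorted by mean", {
  x <- withr::with_seed(2, c(stats::rnorm(500, 20, 3),
                             stats::rnorm(500, 47, 3)))
  m <- fit_mixture(x, 2, seed = 4)
  expect_true(all(diff(m$components$mean) > 0))
  expect_equal(m$components$mean, c(20, 47), tolerance = 0.5)
  expect_equal(m$components$weight, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(m$components$weight), 1, tolerance = 1e-9)
  # deterministic under seed
  m2 <- fit_mixture(x, 2, seed = 4)
  expect_identical(m$components, m2$components)
})

test_that("the EM fitter agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  x <- withr::with_seed(3, c(stats::rnorm(400, 23, 2.5),
                             stats::rnorm(600, 36, 3)))
  m <- fit_mixture(x, 2, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(m$components$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.3)
  expect_equal(sort(m$components$weight), sort(mc$parameters$pro),
               tolerance = 0.03)
})

test_that("too few samples and unlabelled tables are domain errors", {
  expect_error(fit_mixture(stats::rnorm(8), 2), "at least 5\\*k")
  expect_error(population_table(list(a = fixture_mixture(20))),
               "not labelled")
})

test_that("components are labelled by force window with context-aware diagnostics", {
  m <- assign_species(fixture_mixture(c(20.3, 30.1)))
  expect_identical(m$components$label, c("FreeGQ", "GQ@NB"))

  m2 <- assign_species(fixture_mixture(c(23, 36, 47)))
  expect_identical(m2$components$label, c("FreeGQ", "GQ-PDS", "GQ-PDS@NB"))
  expect_true(any(grepl("GQ@NB", m2$diagnostics)))

  m3 <- assign_species(fixture_mixture(c(23, 36, 47)),
                       context = "immobilized_ligand")
  expect_identical(m3$components$label, c("FreeGQ", "GQ@NB", "GQ-PDS@NB"))

  expect_identical(assign_species(fixture_mixture(70))$components$label,
                   "Unassigned")
})

test_that("window collisions keep the component nearest the window centre", {
  m <- assign_species(fixture_mixture(c(33, 38)))
  expect_identical(sum(m$components$label == "GQ-PDS"), 1L)
  expect_identical(sum(m$components$label == "Unassigned"), 1L)
  expect_true(any(grepl("claimed", m$diagnostics)))
})

test_that("population tables render integer percentages that sum to ~100", {
  m1 <- assign_species(fixture_mixture(c(20, 30, 47),
                                       weights = c(0.48, 0.26, 0.26)))
  m2 <- assign_species(fixture_mixture(c(20, 30), weights = c(0.43, 0.57)))
  tbl <- population_table(list(`Immobilized PDS` = m1, `No ligand` = m2))
  expect_identical(tbl$FreeGQ, c(48, 26, 43, 57)[c(1, 3)])
  expect_identical(tbl$`GQ@NB`, c(26, 57))
  expect_identical(tbl$`GQ-PDS@NB`, c(26, NA))
  sums <- rowSums(tbl[, -1], na.rm = TRUE)
  expect_true(all(abs(sums - 100) <= 1))
  md <- format_population_table(tbl)
  expect_true(any(grepl("—", md)))
  # degenerate single-component case
  tbl1 <- population_table(list(x = assign_species(fixture_mixture(20))))
  expect_identical(tbl1$FreeGQ, 100)
})

test_that("rounding keeps percentages within one point of 100 for random weights", {
  withr::with_seed(7, {
    for (i in 1:25) {
      w <- stats::runif(3); w <- w / sum(w)
      m <- assign_species(fixture_mixture(c(20, 30, 47), weights = w))
      tbl <- population_table(list(a = m))
      expect_lte(abs(sum(tbl[1, -1], na.rm = TRUE) - 100), 1)
    }
  })
})

test_that("partition fractions sum to one and recover a symmetric split", {
  x <- withr::with_seed(5, c(stats::rnorm(500, 40, 3),
                             stats::rnorm(500, 55, 3)))
  p <- partition_effects(x, window = c(32, 63), seed = 6)
  expect_identical(p$proximity_fraction + p$confinement_fraction, 1)
  expect_equal(p$proximity_fraction, 0.5, tolerance = 0.05)
  expect_false(p$degenerate)
  # stable across bootstrap seeds for a well-separated mixture
  p2 <- partition_effects(x, window = c(32, 63), seed = 60)
  expect_equal(p$proximity_fraction, p2$proximity_fraction,
               tolerance = 0.03)
  # stochastic-assignment reading of the deconvolution
  p3 <- partition_effects(x, window = c(32, 63), seed = 6,
                          method = "stochastic")
  expect_equal(p3$proximity_fraction, 0.5, tolerance = 0.05)
})

test_that("a unimodal window is flagged degenerate with one dominant component", {
  x <- withr::with_seed(8, stats::rnorm(300, 47, 3))
  p <- partition_effects(x, window = c(32, 63), seed = 9)
  expect_true(p$degenerate)
  expect_gte(max(p$proximity_fraction, p$confinement_fraction), 0.9)
  expect_identical(p$proximity_fraction + p$confinement_fraction, 1)
})

test_that("too few in-window samples is a domain error", {
  expect_error(partition_effects(stats::rnorm(20, 47, 2), seed = 1),
               "at least 30")
})
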