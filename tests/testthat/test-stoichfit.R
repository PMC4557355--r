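cal0 <- monomer_calibration(1000, 250)

test_that("pure monomer brightness is assigned to the monomer component", {
  set.seed(1)
  b <- rnorm(2000, 1000, 250)
  b <- b[b > 0]
  f <- fit_gaussian_mixture(b, cal0)
  expect_gte(coef(f)[["L1"]], 0.95)
  expect_equal(sum(coef(f)), 1, tolerance = 1e-9)
  expect_true(all(coef(f) >= 0))
})

test_that("a 50/50 monomer-dimer mixture is recovered within 0.05", {
  set.seed(2)
  b <- c(rnorm(1000, 1000, 250), rnorm(1000, 2000, 250 * sqrt(2)))
  f <- fit_gaussian_mixture(b, cal0)
  expect_lt(abs(coef(f)[["L1"]] - 0.5), 0.05)
  expect_lt(abs(coef(f)[["L2"]] - 0.5), 0.05)
  expect_error(fit_gaussian_mixture(numeric(0), cal0), "at least")
  expect_error(fit_gaussian_mixture(rnorm(500, 1000, 100), NULL),
               "calibration")
})

test_that("overbright particles are excluded and counted", {
  set.seed(3)
  b <- c(rnorm(500, 1000, 100), rep(9000, 25))
  f <- fit_gaussian_mixture(b, cal0)
  expect_equal(f$excluded, 25L)
})

test_that("mixture fractions are stable under half-bin phase shifts", {
  set.seed(4)
  b <- c(rnorm(1500, 2000, 250 * sqrt(2)), rnorm(1500, 4000, 500))
  f1 <- fit_gaussian_mixture(b, cal0)
  # shifting every brightness by half a bin relocates all histogram edges
  f2 <- fit_gaussian_mixture(b + cal0$sigma1 / 6, cal0)
  shift_effect <- max(abs(coef(f1) - coef(f2)))
  # the half-bin shift also moves the true means by sigma1/6; tolerance 0.02
  # covers the pure binning sensitivity the fit should be robust to
  expect_lt(shift_effect, 0.04)
})

test_that("self-convolution reproduces Gaussian sums on the grid", {
  g <- seq(0, 8000, by = 250 / 20)
  mono <- structure(list(grid = g, density = dnorm(g, 1000, 250)),
                    class = "empirical_pdf")
  mono$density <- mono$density / sum(diff(g) * (mono$density[-1] +
                                                  mono$density[-length(g)]) / 2)
  expect_identical(build_nmer_pdf(mono, 1)$density, mono$density)
  dim2 <- build_nmer_pdf(mono, 2)
  expect_lt(max(abs(dim2$density - dnorm(g, 2000, 250 * sqrt(2)))), 1e-3)
  # convolution moment identity: mean scales with N
  m1 <- sum(g * mono$density) / sum(mono$density)
  for (N in c(2, 3)) {
    pN <- build_nmer_pdf(mono, N)
    mN <- sum(g * pN$density) / sum(pN$density)
    expect_equal(mN, N * m1, tolerance = 1e-4)
  }
  bad <- structure(list(grid = c(0, 1, 3), density = c(1, 1, 1)),
                   class = "empirical_pdf")
  expect_error(build_nmer_pdf(bad, 2), "uniform")
})

test_that("pdf fitting is self-consistent and matches the Gaussian method", {
  set.seed(5)
  ref <- rnorm(1500, 1000, 250)
  ref <- ref[ref > 0]
  f1 <- fit_pdf_mixture(ref, ref, calib = cal0)
  expect_gte(coef(f1)[["L1"]], 0.9)

  f_single <- fit_pdf_mixture(ref, ref, calib = cal0, n_max = 1)
  expect_identical(unname(coef(f_single)), 1)

  # same mixture through both estimators
  b <- c(rnorm(1000, 2000, 250 * sqrt(2)), rnorm(1000, 4000, 500))
  fg <- fit_gaussian_mixture(b, cal0)
  fp <- fit_pdf_mixture(b, ref, calib = cal0)
  expect_lt(max(abs(coef(fg) - coef(fp))), 0.05)
})

test_that("the step census reduces to exact proportions", {
  expect_equal(unname(coef(census_from_steps(c(rep(1, 50), rep(2, 50))))),
               c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(unname(coef(census_from_steps(3L))[3]), 1)
  expect_error(census_from_steps(c(0L, 0L)), "zero")
  f <- census_from_steps(c(1L, 2L, 9L))
  expect_equal(f$excluded, 1L)
  expect_equal(f$n, 2L)
})

test_that("census on high-SNR synthetic traces matches the generator", {
  set.seed(6)
  ph <- photophysics_model(mu1 = 1000, sigma1 = 250)
  opt <- optics_model(fov_px = 1024)
  probs <- stats::setNames(c(0.5, 0.5), c(1, 2))
  truth <- sample_ground_truth(600, probs, 1, opt, ph)
  traces <- synthesize_traces(truth, ph, 500, noise_sd = 1000 / 6)
  res <- count_steps_traces(traces, 1000)
  L <- coef(census_from_steps(res))
  target <- tabulate(truth$labelled_m, 6) / nrow(truth)
  expect_lt(max(abs(L - target)), 0.05)
})

test_that("every estimator returns a normalized nonnegative distribution", {
  set.seed(7)
  b <- c(rnorm(800, 1000, 250), rnorm(800, 4000, 500))
  ref <- rnorm(500, 1000, 250)
  for (f in list(fit_gaussian_mixture(b, cal0),
                 fit_pdf_mixture(b, ref, calib = cal0),
                 census_from_steps(sample(1:6, 200, replace = TRUE)))) {
    expect_true(all(coef(f) >= 0))
    expect_equal(sum(coef(f)), 1, tolerance = 1e-9)
  }
})

test_that("the stoich_fit front door dispatches on method", {
  set.seed(8)
  b <- rnorm(500, 1000, 250)
  expect_identical(coef(stoich_fit(b, cal0, "gaussian")),
                   coef(fit_gaussian_mixture(b, cal0)))
  expect_equal(stoich_fit(c(1L, 1L, 2L), method = "steps")$method, "steps")
})
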