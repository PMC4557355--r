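test_that("labelled counts follow the binomial thinning law", {
  ph <- photophysics_model()
  opt <- optics_model(fov_px = 2048)
  truth <- sample_ground_truth(10000, pure_species(4), label_p = 0.8,
                               optics = opt, photo = ph,
                               min_separation_px = 4, seed = 101)
  expect_true(all(truth$true_n == 4))
  emp <- tabulate(truth$labelled_m + 1L, 5)  # m = 0..4
  pm <- dbinom(0:4, 4, 0.8)
  # each bin within 3 binomial standard errors
  se <- sqrt(10000 * pm * (1 - pm))
  expect_true(all(abs(emp - 10000 * pm) <= 3 * se + 1))
  # chi-square on the joint not rejecting at alpha = 0.01
  cs <- suppressWarnings(chisq.test(emp, p = pm))
  expect_gt(cs$p.value, 0.01)
})

test_that("degenerate labelling and species choices behave exactly", {
  opt <- optics_model(fov_px = 256)
  truth <- sample_ground_truth(200, pure_species(3), label_p = 1,
                               optics = opt, seed = 7)
  expect_true(all(truth$labelled_m == truth$true_n))
  truth1 <- sample_ground_truth(100, pure_species(1), label_p = 0.5,
                                optics = opt, seed = 8)
  expect_true(all(truth1$true_n == 1))
  # pairwise separation respected
  d2 <- as.matrix(dist(cbind(truth1$x, truth1$y)))
  diag(d2) <- Inf
  expect_gte(min(d2), 6)
})

test_that("identical seeds reproduce truth, traces and movie bit for bit", {
  ph <- photophysics_model()
  opt <- optics_model(fov_px = 48)
  ds1 <- synthetic_dataset(6, pure_species(2), 0.8, opt, ph, n_frames = 40,
                           noise_sd = 100, render = TRUE, seed = 5)
  ds2 <- synthetic_dataset(6, pure_species(2), 0.8, opt, ph, n_frames = 40,
                           noise_sd = 100, render = TRUE, seed = 5)
  expect_identical(ds1$truth, ds2$truth)
  expect_identical(ds1$traces, ds2$traces)
  expect_identical(as.numeric(ds1$stack), as.numeric(ds2$stack))
})

test_that("expected initial trace level is m times the monomer brightness", {
  ph <- photophysics_model(mu1 = 1000, sigma1 = 250)
  opt <- optics_model(fov_px = 1024)
  truth <- sample_ground_truth(1500, pure_species(3), label_p = 1,
                               optics = opt, photo = ph, seed = 21)
  b <- true_brightness(truth)
  # mean brightness ~ 3 * mu1 within 3 s.e. (truncation bias at mu/sigma = 4
  # is ~0.13% and far below the tolerance)
  se <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(b) - 3000), 3 * se + 3000 * 0.002)
})

test_that("noiseless traces are staircases with labelled_m merged steps", {
  ph <- photophysics_model()
  opt <- optics_model(fov_px = 256)
  truth <- sample_ground_truth(40, pure_species(3), label_p = 1,
                               optics = opt, photo = ph, seed = 31)
  traces <- synthesize_traces(truth, ph, n_frames = 500, noise_sd = 0)
  for (j in seq_along(traces)) {
    tr <- as.numeric(traces[[j]])
    i <- attr(traces, "truth_index")[j]
    f <- floor(truth$bleach_frames[[i]])
    n_down <- sum(diff(tr) < 0)
    expect_equal(n_down, length(unique(f[f >= 1 & f < 500])))
    # after the last bleach frame the signal is exactly zero
    if (max(f) < 500) expect_identical(tr[max(f, 1) + 1], 0)
  }
})

test_that("rendered movies have Poisson statistics around the forward model", {
  ph <- photophysics_model(mu1 = 800, sigma1 = 0, bleach_mean_frames = 1e6,
                           background_rate = 3, read_noise_sd = 0)
  opt <- optics_model(psf_sigma_px = 1.2, fov_px = 32)
  # background only
  empty <- sample_ground_truth(1, pure_species(1), 1, opt, ph, seed = 1)
  empty <- empty[0, ]
  mov0 <- render_movie(empty, opt, ph, n_frames = 300, seed = 2)
  se0 <- sqrt(3 / (300 * 32 * 32))
  expect_lt(abs(mean(mov0) - 3), 3 * se0)

  # one never-bleaching fluorophore: integrated excess counts ~ brightness
  one <- sample_ground_truth(1, pure_species(1), 1, opt, ph, seed = 3)
  mov1 <- render_movie(one, opt, ph, n_frames = 400, seed = 4)
  spot_sum <- apply(mov1, 3, sum) - 3 * 32 * 32
  b_true <- one$per_fluor_brightness[[1]]
  se1 <- sd(spot_sum) / sqrt(length(spot_sum))
  expect_lt(abs(mean(spot_sum) - b_true), 3 * se1)
})

test_that("bleaching lifetimes are exponential with the configured mean", {
  ph <- photophysics_model(bleach_mean_frames = 50)
  opt <- optics_model(fov_px = 2048)
  truth <- sample_ground_truth(1000, pure_species(1), 1, opt, ph,
                               min_separation_px = 4, seed = 77)
  lifetimes <- unlist(truth$bleach_frames)
  expect_lt(abs(mean(lifetimes) - 50), 3 * 50 / sqrt(length(lifetimes)))
})

test_that("movie, trace and truth round-trip through their file formats", {
  ph <- photophysics_model()
  opt <- optics_model(fov_px = 32)
  ds <- synthetic_dataset(4, pure_species(2), 0.8, opt, ph, n_frames = 12,
                          noise_sd = 50, render = TRUE, seed = 9)
  tf <- tempfile(fileext = ".tif")
  write_movie_tiff(ds$stack, tf)
  back <- read_movie_tiff(tf)
  expect_equal(dim(back), dim(ds$stack))
  # 16-bit storage: integer-rounded counts survive
  expect_lt(max(abs(back - round(pmin(ds$stack, 65535)))), 1.5)

  cf <- tempfile(fileext = ".csv")
  write_traces_csv(ds$traces, cf)
  traces2 <- read_traces_csv(cf)
  expect_equal(length(traces2), length(ds$traces))
  expect_equal(as.numeric(traces2[[1]]), as.numeric(ds$traces[[1]]),
               tolerance = 1e-9)

  jf <- tempfile(fileext = ".json")
  write_truth_json(ds$truth, jf)
  obj <- jsonlite::read_json(jf)
  expect_equal(length(obj$particles), nrow(ds$truth))
  expect_equal(obj$particles[[2]]$true_n, ds$truth$true_n[2])
  unlink(c(tf, cf, jf))
})
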