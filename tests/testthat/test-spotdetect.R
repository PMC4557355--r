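make_frame <- function(emitters, fov = 48, bg = 5, psf = 1.2,
                       poisson = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(bg, fov, fov)
  for (i in seq_len(nrow(emitters))) {
    ix <- 0:(fov - 1)
    fx <- pnorm(ix + 0.5, emitters$x[i], psf) - pnorm(ix - 0.5, emitters$x[i], psf)
    fy <- pnorm(ix + 0.5, emitters$y[i], psf) - pnorm(ix - 0.5, emitters$y[i], psf)
    img <- img + emitters$b[i] * outer(fx, fy)
  }
  if (poisson) img <- matrix(rpois(fov * fov, img), fov, fov)
  img
}

par0 <- detection_params(smoothing_sigma_px = 1.2, threshold = 20,
                        min_separation_px = 5, fit_window_px = 11)

test_that("blank frames yield no detections", {
  set.seed(1)
  frame <- matrix(rpois(48 * 48, 5), 48, 48)
  expect_equal(nrow(detect_spots(frame, par0)), 0)
})

test_that("well-separated emitters are each found within a pixel", {
  em <- data.frame(x = c(15.3, 25.3), y = c(20.2, 20.2), b = c(3000, 3000))
  frame <- make_frame(em, seed = 2)
  sp <- detect_spots(frame, par0)
  expect_equal(nrow(sp), 2)
  for (i in 1:2) {
    d <- sqrt((em$x - sp$x[i])^2 + (em$y - sp$y[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("sub-threshold emitters are rejected", {
  em <- data.frame(x = 20, y = 20, b = 80)  # peak ~ 9 counts << threshold
  frame <- make_frame(em, seed = 3)
  expect_equal(nrow(detect_spots(frame, par0)), 0)
})

test_that("noiseless Gaussian spots are fitted essentially exactly", {
  em <- data.frame(x = 21.37, y = 19.84, b = 2500)
  frame <- make_frame(em, poisson = FALSE)
  fit <- fit_spot_mle(frame, 21, 20, window = 13, psf_sigma = 1.0)
  expect_true(fit$ok)
  expect_equal(fit$x, 21.37, tolerance = 1e-4)
  expect_equal(fit$y, 19.84, tolerance = 1e-4)
  expect_equal(fit$sigma_fit, 1.2, tolerance = 1e-3)
  expect_equal(fit$brightness, 2500, tolerance = 1e-3)
  expect_equal(fit$background, 5, tolerance = 1e-3)
})

test_that("flat windows report no signal", {
  flat <- matrix(7, 31, 31)
  fit <- fit_spot_mle(flat, 15, 15, window = 11)
  expect_false(fit$ok)
  expect_equal(fit$brightness, 0)
  expect_equal(fit$background, 7)
  expect_error(fit_spot_mle(matrix(c(NA, rpois(120, 5)), 11, 11), 5, 5,
                            window = 11), "non-finite")
  expect_error(fit_spot_mle(matrix(5, 20, 20), 2, 2, window = 11), "window")
})

test_that("Poisson-noise localization is unbiased and precise", {
  set.seed(9)
  em <- data.frame(x = 20.4, y = 20.6, b = 2500)  # peak ~ 280 over bg 5
  dx <- b_rel <- numeric(60)
  for (i in 1:60) {
    frame <- make_frame(em)
    fit <- fit_spot_mle(frame, 20, 21, window = 13)
    dx[i] <- fit$x - em$x
    b_rel[i] <- fit$brightness / em$b
  }
  expect_lt(median(abs(dx)), 0.1)
  expect_lt(abs(median(b_rel) - 1), 0.02)
})

test_that("localization error shrinks as photons increase", {
  set.seed(10)
  err <- vapply(c(400, 1600, 6400), function(b) {
    em <- data.frame(x = 20.4, y = 20.6, b = b)
    median(replicate(40, {
      fit <- fit_spot_mle(make_frame(em), 20, 21, window = 13)
      sqrt((fit$x - em$x)^2 + (fit$y - em$y)^2)
    }))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("detection plus fitting recovers a rendered field", {
  ph <- photophysics_model(mu1 = 2000, sigma1 = 200,
                           bleach_mean_frames = 1e5, background_rate = 5,
                           read_noise_sd = 1)
  opt <- optics_model(psf_sigma_px = 1.2, fov_px = 96)
  set.seed(11)
  truth <- sample_ground_truth(25, pure_species(1), 1, opt, ph,
                               min_separation_px = 8)
  mov <- render_movie(truth, opt, ph, n_frames = 6, seed = 12)
  mm <- measure_movie(mov, detection_params(1.2, threshold = 25,
                                            min_separation_px = 5,
                                            fit_window_px = 11))
  # >= 95% of emitters recovered
  found <- vapply(seq_len(nrow(truth)), function(j) {
    any((mm$spots$x - truth$x[j])^2 + (mm$spots$y - truth$y[j])^2 < 9)
  }, logical(1))
  expect_gte(mean(found), 0.95)
  # < 2% spurious (no emitter within 3 px)
  spurious <- vapply(seq_len(nrow(mm$spots)), function(i) {
    all((mm$spots$x[i] - truth$x)^2 + (mm$spots$y[i] - truth$y)^2 > 9)
  }, logical(1))
  expect_lte(sum(spurious), max(0, ceiling(0.02 * nrow(truth))))
  # fitted brightness tracks the generator's per-particle brightness
  ib <- initial_brightness(mm$traces, monomer_step_counts = 2000)
  match_id <- vapply(seq_len(nrow(mm$spots)), function(i)
    which.min((truth$x - mm$spots$x[i])^2 + (truth$y - mm$spots$y[i])^2),
    integer(1))
  tb <- vapply(match_id, function(j) sum(truth$per_fluor_brightness[[j]]),
               numeric(1))
  expect_lt(median(abs(ib / tb - 1)), 0.05)
})
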