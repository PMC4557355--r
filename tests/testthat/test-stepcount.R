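test_that("filter leaves constant traces untouched and preserves ideal edges", {
  p <- ck_params()
  x <- rep(5, 60)
  expect_equal(ck_filter(x, p), x, ignore_attr = TRUE)

  # ideal noiseless two-level step: at most one frame off the true levels
  y <- c(rep(10, 50), rep(2, 50))
  f <- ck_filter(y, p)
  off <- sum(abs(f - 10) > 1e-9 & abs(f - 2) > 1e-9)
  expect_lte(off, 1)
  # edge position preserved: the drop still happens between frames 50 and 51
  expect_gt(f[50], 6)
  expect_lt(f[51], 6)
})

test_that("filter suppresses white noise at least as well as a running mean", {
  set.seed(3)
  p <- ck_params(window_frames = 4)
  x <- rnorm(1000, 0, 1)
  f <- ck_filter(x, p)
  expect_lt(var(f[10:990]), 1.5 * 1 / 4)
})

test_that("filter is idempotent-ish on piecewise-constant signals", {
  set.seed(4)
  x <- make_staircase(3, 1000, noise_sd = 0)
  f1 <- ck_filter(x, ck_params())
  f2 <- ck_filter(f1, ck_params())
  expect_lt(mean(abs(f2 - f1) > 1e-9), 0.01)
})

test_that("filter rejects unusable traces", {
  expect_error(ck_filter(rep(1, 5), ck_params(window_frames = 4)), "short")
  expect_error(ck_filter(c(rep(1, 30), NA), ck_params()), "finite")
})

test_that("noiseless staircases are counted exactly", {
  set.seed(5)
  x <- make_staircase(4, 1000, noise_sd = 0)
  r <- count_steps(ck_filter(x, ck_params()), 1000 / max(x), raw = x)
  expect_equal(r$n_steps, 4)
  expect_equal(length(r$change_points), 4)
  expect_true(all(abs(r$step_sizes - 0.25) < 1e-6))
  expect_true(r$complete)

  # monotone ramp without threshold-crossing jumps: zero steps
  ramp <- seq(1000, 900, length.out = 200)
  r0 <- count_steps(ck_filter(ramp, ck_params()), 0.5)
  expect_equal(r0$n_steps, 0)

  expect_error(count_steps(rep(0, 50), 0.5), "all-zero")
  expect_error(count_steps(rep(1, 50), 0), "monomer_step")
})

test_that("step counting is at least 80% exact at step-to-noise 3", {
  set.seed(6)
  for (m in 1:4) {
    hits <- replicate(120, {
      x <- make_staircase(m, 1000, noise_sd = 1000 / 3)
      count_staircase(x) == m
    })
    expect_gte(mean(hits), 0.8)
  }
})

test_that("counted steps never exceed frames minus one", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(60, 0, 1) + make_staircase(2, 5, n_frames = 60, min_sep = 4)
    r <- count_steps(ck_filter(x, ck_params(window_frames = 3)), 0.2,
                     raw = x)
    expect_lte(r$n_steps, 59)
  }
})

test_that("step sizes do not depend on the oligomeric state", {
  set.seed(8)
  ph <- photophysics_model(mu1 = 1000, sigma1 = 250)
  opt <- optics_model(fov_px = 1024)
  results <- list()
  for (m in 1:4) {
    truth <- sample_ground_truth(150, pure_species(m), 1, opt, ph)
    traces <- synthesize_traces(truth, ph, 500, noise_sd = 1000 / 3)
    results <- c(results, count_steps_traces(traces, 1000))
  }
  tab <- stepsize_table(results, units = "counts")
  expect_true(all(tab$n_steps %in% 1:6))
  tab14 <- tab[tab$n_steps %in% 1:4 & tab$n_particles >= 20, ]
  expect_gte(nrow(tab14), 3)
  # per-fluorophore drops average mu1 in every group: oligomerization does
  # not change single-fluorophore brightness
  for (i in seq_len(nrow(tab14))) {
    se <- tab14$sd_size[i] / sqrt(tab14$n_sizes[i])
    expect_lt(abs(tab14$mean_size[i] - 1000), 4 * se + 50)
  }
})

test_that("constructed step sizes are reported per group exactly", {
  r1 <- list(n_steps = 1L, step_sizes = 1.0)
  r2 <- list(n_steps = 1L, step_sizes = 1.0)
  r3 <- list(n_steps = 2L, step_sizes = c(2.0, 2.0))
  tab <- stepsize_table(list(r1, r2, r3), units = "normalized")
  expect_equal(tab$mean_size, c(1.0, 2.0))
  expect_equal(tab$n_particles, c(2L, 1L))
})
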