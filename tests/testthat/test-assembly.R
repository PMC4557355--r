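test_that("binding radius inverts the Smoluchowski rate", {
  D <- 62.5
  r <- 0.07
  k <- 4 * pi * D * r
  expect_equal(binding_radius(k, D), r, tolerance = 1e-12)
  expect_equal(binding_radius(2 * k, D), 2 * r, tolerance = 1e-12)
  expect_equal(binding_radius(k, D, floor_radius = 0.1), 0.1)
  expect_equal(binding_radius(0, D), 0)
})

quick_cfg <- function(...) {
  args <- list(box_side_um = 3, n_bax = 80, n_cbid = 160, n_luv = 100,
               duration_s = 2, sample_dt_s = 0.25)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(assembly_config, args)
}

test_that("mass is conserved and runs are reproducible", {
  tc <- suppressWarnings(run_assembly(quick_cfg(seed = 3)))
  hist <- attr(tc, "size_hist")
  bound <- as.numeric(hist %*% seq_len(ncol(hist)))
  expect_true(all(tc$soluble_bax + bound == 80))
  expect_true(all(tc$soluble_cbid >= 0 & tc$soluble_cbid <= 160))
  tc2 <- suppressWarnings(run_assembly(quick_cfg(seed = 3)))
  expect_identical(as.data.frame(tc), as.data.frame(tc2))
  expect_identical(attr(tc, "size_hist"), attr(tc2, "size_hist"))
  tc3 <- suppressWarnings(run_assembly(quick_cfg(seed = 4)))
  expect_false(identical(as.data.frame(tc), as.data.frame(tc3)))
})

test_that("without any recruitment path no vesicle ever carries protein", {
  cfg <- quick_cfg(n_cbid = 1, k_bax_on_cbid = 0, k_bax_on_bax = 0, seed = 5)
  tc <- suppressWarnings(run_assembly(cfg))
  expect_true(all(tc$occupied_luvs == 0))
  expect_true(all(tc$soluble_bax == 80))
  expect_equal(luv_occupancy_fraction(tc, 0), 0)
})

test_that("occupancy grows monotonically under irreversible binding", {
  cfg <- quick_cfg(k_mono_off = 0, k_shrink = 0, k_cbid_off = 0, seed = 6)
  tc <- suppressWarnings(run_assembly(cfg))
  expect_true(all(diff(tc$occupied_luvs) >= 0))
  expect_error(luv_occupancy_fraction(tc, 100), "range")
})

test_that("the dt stability warning fires when steps outrun the vesicle", {
  expect_warning(run_assembly(quick_cfg(seed = 1, D_cbid = 100)),
                 "rms step")
})

test_that("Gillespie reference obeys detailed balance and its limits", {
  # closed-form stationary mean of the two-state birth-death chain
  eq <- equilibrium_bound_fraction(k_on = 80, k_off = 60, n_a = 50,
                                   n_l = 20, volume = 27)
  ssa <- well_mixed_reference(80, 60, 50, 20, 27, t_end = 150,
                              stationary_from = 10, seed = 8)
  expect_lt(abs(ssa$bound_fraction - eq) / eq, 0.05)
  # no dissociation: everything ends up bound
  ssa0 <- well_mixed_reference(80, 0, 30, 20, 27, t_end = 50, seed = 9)
  expect_equal(ssa0$bound_fraction, 1)
  expect_equal(equilibrium_bound_fraction(80, 0, 30, 20, 27), 1)
})

test_that("spatial engine matches the well-mixed oracle in the fast limit", {
  r <- 0.1; dt <- 5e-5
  k_eff <- wellmixed_on_rate(r, dt)
  nA <- 50; nL <- 20; V <- 27; koff <- 60
  eq <- equilibrium_bound_fraction(k_eff, koff, nA, nL, V)
  for (s in 1:2) {
    cfg <- assembly_config(box_side_um = 3, n_bax = 0, n_cbid = nA,
                           n_luv = nL, duration_s = 1.5, sample_dt_s = 0.01,
                           D_bax = 6000, D_cbid = 10000, D_luv = 250,
                           k_cbid_off = koff, seed = s)
    tc <- suppressWarnings(run_assembly(cfg))
    w <- tc$time >= 0.5
    bf <- mean((nA - tc$soluble_cbid[w]) / nA)
    expect_lt(abs(bf - eq) / eq, 0.05)
  }
})

test_that("even-size enrichment rises with the stabilization multiplier", {
  # short runs are noisy; average the ratio over three seeds per multiplier
  ratios <- vapply(c(1, 3, 10), function(st) {
    mean(vapply(11:13, function(s) {
      tc <- suppressWarnings(run_assembly(quick_cfg(even_stabilization = st,
                                                    duration_s = 4,
                                                    seed = s)))
      even_odd_mass_ratio(tc)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_gt(ratios[3], 2)
})

test_that("more activator binds more protein at a fixed early time", {
  bound_at <- function(n_cbid) {
    cfg <- assembly_config(box_side_um = 3, n_bax = 80, n_cbid = n_cbid,
                           n_luv = 100, duration_s = 0.4,
                           sample_dt_s = 0.1, k_bax_on_bax = 0, seed = 12)
    tc <- suppressWarnings(run_assembly(cfg))
    80 - tc$soluble_bax[nrow(tc)]
  }
  expect_gt(bound_at(160), bound_at(10))
})

test_that("timecourse export writes complete CSV", {
  tc <- suppressWarnings(run_assembly(quick_cfg(seed = 13)))
  f <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(tc))
  expect_true(all(c("time", "soluble_bax", "size_1") %in% names(df)))
  unlink(f)
})
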