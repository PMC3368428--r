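test_that("paradigm defaults give thirty onsets spaced by the ISI", {
  p <- make_paradigm()
  on <- onset_times(p)
  expect_length(on, 30)
  expect_equal(on[1:3], c(60, 130, 200))
  expect_equal(paradigm_duration_s(p), 60 + 30 * 70)

  p1 <- make_paradigm(n_trials = 1)
  expect_equal(onset_times(p1), 60)
})

test_that("degenerate or unknown paradigm settings are rejected", {
  expect_error(make_paradigm(isi_s = 0), "positive")
  expect_error(make_paradigm(banana = 3), "unknown")
  expect_error(make_paradigm(stim_duration_s = -1), "positive")
  expect_error(make_paradigm(ois_trial_window_s = 10), "cover")
})

test_that("generated fields have the region sign structure and exact HbT closure", {
  p <- make_paradigm(n_trials = 2)
  f <- generate_haemodynamics(p, grid_px = c(64, 64),
                              duration_s = p$baseline_s + p$isi_s)
  pos <- as.vector(f$region_masks[[1]])
  neg <- as.vector(f$region_masks[[2]])
  nt <- dim(f$d_hbt)[1]
  hbt <- matrix(f$d_hbt, nt); hbr <- matrix(f$d_hbr, nt)
  expect_true(all(apply(hbt[, pos], 2, max) > 0))
  expect_true(all(apply(hbr[, pos], 2, min) < 0))
  expect_true(all(apply(hbt[, neg], 2, min) < 0))
  expect_true(all(apply(hbr[, neg], 2, max) > 0))
  # closure is exact by construction
  expect_identical(max(abs(f$d_hbt - (f$d_hbo2 + f$d_hbr))), 0)
  # zero outside the tapered regions
  dy <- outer(1:64, rep(1, 64)); dx <- t(dy)
  far <- as.vector(sqrt((dy - 22)^2 + (dx - 22)^2) > 17 &
                     sqrt((dy - 44)^2 + (dx - 44)^2) > 19)
  expect_identical(max(abs(hbt[, far])), 0)
})

test_that("empty region lists, overlaps and out-of-grid regions are handled", {
  p <- make_paradigm(n_trials = 1)
  f0 <- generate_haemodynamics(p, regions = list(), grid_px = c(12, 10),
                               duration_s = 20)
  expect_equal(dim(f0$d_hbt), c(round(20 * 8), 12, 10))
  expect_identical(max(abs(f0$d_hbt)), 0)

  r1 <- region_spec(c(20, 20), 10, "positive", 5, -3)
  r2 <- region_spec(c(25, 25), 10, "negative", -2, 1)
  expect_error(generate_haemodynamics(p, list(r1, r2), grid_px = c(64, 64)),
               "overlap")
  expect_error(generate_haemodynamics(p, list(r1), grid_px = c(24, 24)),
               "beyond")
  expect_error(region_spec(c(5, 5), 3, "positive", -5, -3), "positive region")
  expect_error(region_spec(c(5, 5), 3, "negative", -5, -3), "negative region")
})

test_that("noisy generation is seed-deterministic and trial averaging reduces variance ~ n_trials", {
  p <- make_paradigm(n_trials = 30, isi_s = 20, stim_duration_s = 4,
                     ois_trial_window_s = 16, ois_prestim_s = 2)
  a <- generate_haemodynamics(p, regions = list(), grid_px = c(3, 3),
                              noise_uM = 1, seed = 42)
  b <- generate_haemodynamics(p, regions = list(), grid_px = c(3, 3),
                              noise_uM = 1, seed = 42)
  expect_identical(a$d_hbr, b$d_hbr)

  folded <- fold_trials(a$d_hbr, p, rate_hz = 8)
  v_raw <- mean(apply(matrix(a$d_hbr, dim(a$d_hbr)[1]), 2, var))
  v_fold <- mean(apply(matrix(folded, dim(folded)[1]), 2, var))
  expect_equal(attr(folded, "n_trials_used"), 30)
  expect_lt(abs(v_raw / v_fold - 30), 0.2 * 30)
})

test_that("forward-rendered stacks have four bands at the OIS rate and the expected signs", {
  w <- fx_positive_world()
  expect_s3_class(w$stack, "ois_stack")
  expect_equal(dim(w$stack$attenuation)[1], 4)
  expect_equal(dim(w$stack$attenuation)[2], round(70 * 8))
  expect_equal(w$stack$rate_hz, 8)

  # zero field with no noise renders identically zero attenuation
  p1 <- make_paradigm(n_trials = 1)
  f0 <- generate_haemodynamics(p1, regions = list(), grid_px = c(6, 6),
                               duration_s = 10)
  s0 <- render_wavelength_stack(f0, w$tissue, fx_lut_hom(), fx_optics())
  expect_identical(max(abs(s0$attenuation)), 0)

  # a uniform HbT increase at fixed saturation attenuates at all four bands
  fu <- f0
  fu$d_hbt[] <- 3; fu$d_hbo2[] <- 1.5; fu$d_hbr[] <- 1.5
  su <- render_wavelength_stack(fu, w$tissue, fx_lut_hom(), fx_optics())
  expect_true(all(su$attenuation > 0))
})

test_that("synthetic fMRI has the paradigm frame count and is seed-deterministic", {
  p <- make_paradigm()
  regions <- list(region_spec(c(5, 5), 3, "positive", 5, -3),
                  region_spec(c(13, 12), 3, "negative", -2.5, 1.5,
                              peak_time_s = 8, depth = "deep"))
  f <- generate_haemodynamics(p, regions, grid_px = c(16, 16),
                              rate_hz = 1)
  base <- fx_positive_world()$baseline
  fm <- generate_fmri(f, base, fx_mr(), fx_blut(), noise_sd = 0.003,
                      seed = 9, paradigm = p)
  expect_equal(dim(fm$data), c(60 + 30 * 70, 64, 64))
  fm2 <- generate_fmri(f, base, fx_mr(), fx_blut(), noise_sd = 0.003,
                       seed = 9, paradigm = p)
  expect_identical(fm$data, fm2$data)

  # null forward model: zero field and zero noise give a constant series
  f0 <- generate_haemodynamics(p, regions = list(), grid_px = c(8, 8),
                               rate_hz = 1, duration_s = 80)
  fm0 <- generate_fmri(f0, base, fx_mr(), fx_blut(), noise_sd = 0, seed = 1)
  expect_identical(max(fm0$data), min(fm0$data))

  # a field shorter than the paradigm is rejected
  fshort <- generate_haemodynamics(p, regions = list(), grid_px = c(8, 8),
                                   rate_hz = 1, duration_s = 100)
  expect_error(generate_fmri(fshort, base, fx_mr(), fx_blut(),
                             paradigm = p), "cover")
})
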