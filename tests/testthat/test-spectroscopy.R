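test_that("baseline concentrations follow the blood-volume anchor and saturation split", {
  op <- fx_optics()
  b <- baseline_concentrations(homogeneous_tissue(), op)
  expect_equal(b$hbt0, 104)
  expect_equal(b$hbo2_0, 52)
  expect_equal(b$hbr0, 52)

  het <- baseline_concentrations(heterogeneous_tissue(), op)
  expect_equal(het$hbt0[4], 104 * 4 / 6, tolerance = 1e-12)
  expect_equal(het$hbt0[1], 104)

  full <- baseline_concentrations(heterogeneous_tissue(), op, y0 = 1)
  expect_true(all(full$hbr0 == 0))
  expect_error(baseline_concentrations(homogeneous_tissue(), op,
                                       blood_hbt_uM = -1), "positive")
})

test_that("the Hill dissociation curve behaves at its anchors", {
  h <- hill_params()
  expect_equal(saturation_from_po2(h$p50_mmHg, h), 0.5)
  expect_gt(saturation_from_po2(1e6, h), 0.999)
  expect_equal(saturation_from_po2(0, h), 0)
  # rat parenchymal oxygen tension ~40 mmHg sits near half saturation
  expect_equal(saturation_from_po2(40, h), 0.5333, tolerance = 1e-3)
  expect_error(saturation_from_po2(-1, h), "non-negative")
  expect_error(hill_params(p50_mmHg = 0), "positive")
})

test_that("zero attenuation inverts to zero concentrations in one iteration", {
  w <- fx_positive_world()
  A0 <- array(0, dim = c(4, 5, 3, 3))
  rec <- plsa_invert(A0, fx_lut_hom(), w$baseline)
  expect_identical(max(abs(rec$d_hbo2)), 0)
  expect_identical(max(abs(rec$d_hbr)), 0)
  expect_identical(max(abs(rec$d_hbt)), 0)
  expect_true(all(rec$iterations == 1L))
  expect_true(all(rec$converged))
})

test_that("noise-free forward-rendered stacks invert back within 5%", {
  w <- fx_positive_world()
  rec <- plsa_invert(w$stack, fx_lut_hom(), w$baseline)
  sel <- abs(w$field$d_hbr) > 0.3
  expect_lt(max(abs(rec$d_hbr[sel] - w$field$d_hbr[sel]) /
                  abs(w$field$d_hbr[sel])), 0.05)
  sel <- abs(w$field$d_hbo2) > 0.5
  expect_lt(max(abs(rec$d_hbo2[sel] - w$field$d_hbo2[sel]) /
                  abs(w$field$d_hbo2[sel])), 0.05)
  expect_true(all(rec$converged))
  # closure holds exactly on output
  expect_identical(max(abs(rec$d_hbt - (rec$d_hbo2 + rec$d_hbr))), 0)
})

test_that("the inversion is linear in the small-signal limit", {
  w <- fx_positive_world()
  # decay-phase frames (|dHbr| of order 0.5 uM): genuinely small-signal
  A <- w$stack$attenuation[, 160:210, , , drop = FALSE]
  full <- plsa_invert(A, fx_lut_hom(), w$baseline)
  half <- plsa_invert(A / 2, fx_lut_hom(), w$baseline)
  sel <- abs(full$d_hbr) > 0.2
  expect_gt(sum(sel), 100)
  expect_lt(max(abs(2 * half$d_hbr[sel] - full$d_hbr[sel]) /
                  abs(full$d_hbr[sel])), 0.01)
})

test_that("a deep Hbr increase is recovered larger (and highly correlated) under the heterogeneous model", {
  op <- fx_optics()
  p <- make_paradigm(n_trials = 1)
  # deep-only Hbr increase (negative-region signature)
  reg <- region_spec(c(9, 9), 5, "negative", hbt_peak_uM = -2.5,
                     hbr_peak_uM = 1.5, peak_time_s = 8, depth = "deep")
  f <- trial_window_field(p, list(reg), grid_px = c(18, 18))
  tis_het <- heterogeneous_tissue()
  stack <- render_wavelength_stack(f, tis_het, fx_lut_het(), op)

  rec_het <- plsa_invert(stack, fx_lut_het(),
                         baseline_concentrations(tis_het, op))
  rec_hom <- plsa_invert(stack, fx_lut_hom(),
                         baseline_concentrations(homogeneous_tissue(), op))
  mask <- f$region_masks[[1]]
  ts_het <- region_timeseries(rec_het$d_hbr, mask)
  ts_hom <- region_timeseries(rec_hom$d_hbr, mask)
  expect_gt(max(abs(ts_het)), max(abs(ts_hom)))
  # the tissue-model effect is primarily one of scaling
  expect_gt(cor(ts_het, ts_hom), 0.95)
})

test_that("stacks that do not match the LuT are rejected", {
  w <- fx_positive_world()
  bad <- w$stack$attenuation[1:3, 1:4, , , drop = FALSE]
  expect_error(plsa_invert(bad, fx_lut_hom(), w$baseline), "bands")
  nf <- w$stack$attenuation[, 1:2, 1:2, 1:2, drop = FALSE]
  nf[1] <- NA
  expect_error(plsa_invert(nf, fx_lut_hom(), w$baseline), "finite")
})
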