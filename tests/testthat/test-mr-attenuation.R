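test_that("the baseline state anchors dR2* to zero by construction", {
  mr <- mr_config(n_protons = 1500, n_geom = 2, seed = 3)
  expect_identical(as.numeric(ev_delta_r2star(0.06, 0.5, 10, mr)), 0)
  # the LuT accessor is likewise anchored, at and between nodes
  blut <- fx_blut()
  expect_equal(as.numeric(bold_delta_r2star(blut, 0.06, 0.5, 10)), 0)
  expect_equal(as.numeric(bold_delta_r2star(blut, 0.065, 0.52, 10,
                                            v0 = 0.065, y0 = 0.52)), 0)
})

test_that("dR2* grows with deoxygenation and with blood volume (paired seeds)", {
  blut <- fx_blut()
  iv0 <- which(blut$v_grid == 0.06)
  ir <- which(blut$r_grid == 10)
  # decreasing Y at fixed V: R2* non-decreasing (phases shared along Y)
  curve_y <- blut$r2star[iv0, rev(seq_along(blut$y_grid)), ir]
  expect_true(all(diff(curve_y) >= -1e-9))
  # increasing V at fixed Y < y0 (common random numbers across V)
  iy <- which.min(abs(blut$y_grid - 0.4))
  curve_v <- blut$r2star[, iy, ir]
  jitter_ok <- diff(curve_v) > -0.05 * max(abs(curve_v))
  expect_true(all(jitter_ok))
})

test_that("the accessor reproduces stored nodes exactly and clips out-of-grid queries", {
  blut <- fx_blut()
  iv <- 3; iy <- 5; ir <- 2
  got <- bold_delta_r2star(blut, blut$v_grid[iv], blut$y_grid[iy],
                           blut$r_grid[ir])
  expect_equal(as.numeric(got),
               blut$r2star[iv, iy, ir] -
                 blut$r2star[which(blut$v_grid == blut$v0),
                             which(blut$y_grid == blut$y0), ir])
  out <- bold_delta_r2star(blut, 0.5, 0.5, 10)
  expect_equal(attr(out, "clipped"), 1)
})

test_that("dR2* is approximately linear in (1-Y)V over the physiological range", {
  blut <- fx_blut()
  ir <- which(blut$r_grid == 10)
  sel_v <- blut$v_grid >= 0.04 & blut$v_grid <= 0.09
  sel_y <- blut$y_grid >= 0.3 & blut$y_grid <= 0.7
  g <- expand.grid(v = blut$v_grid[sel_v], y = blut$y_grid[sel_y])
  dr2 <- mapply(function(v, y)
    as.numeric(bold_delta_r2star(blut, v, y, 10)), g$v, g$y)
  x <- (1 - g$y) * g$v
  fit <- lm(dr2 ~ x)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("gradient-echo dR2* plateaus above 15 um and is non-decreasing over 3-20 um", {
  mr <- mr_config(n_protons = 8000, n_geom = 10, seed = 3)
  d15 <- as.numeric(ev_delta_r2star(0.06, 0.4, 15, mr))
  d20 <- as.numeric(ev_delta_r2star(0.06, 0.4, 20, mr))
  expect_lt(abs(d20 - d15) / abs(d15), 0.10)
  d3 <- as.numeric(ev_delta_r2star(0.06, 0.4, 3, mr))
  d10 <- as.numeric(ev_delta_r2star(0.06, 0.4, 10, mr))
  # non-decreasing within MC jitter (common random numbers across radii)
  expect_gt(d10 - d3, -0.1 * d10)
  expect_gt(d20 - d10, -0.1 * d20)
})

test_that("the diffusive MC agrees with a no-diffusion oracle at large radius", {
  mr <- mr_config(n_protons = 6000, n_geom = 10, seed = 3)
  mc <- as.numeric(ev_delta_r2star(0.06, 0.4, 50, mr))
  oracle <- static_dephasing_oracle(0.06, 0.4, 50, mr, n_geom = 10,
                                    n_pos = 10000)
  expect_lt(abs(mc - oracle$mean) / oracle$mean, 0.15)
})

test_that("wall reflection is a small correction at physiological volume fractions", {
  mr <- mr_config(n_protons = 8000, n_geom = 8, seed = 3)
  with_r <- as.numeric(ev_delta_r2star(0.06, 0.4, 10, mr, reflect = TRUE))
  no_r <- as.numeric(ev_delta_r2star(0.06, 0.4, 10, mr, reflect = FALSE))
  expect_lt(abs(with_r - no_r) / abs(with_r), 0.05)
})

test_that("BOLD predictions carry the sign structure and envelope containment", {
  w <- fx_positive_world()
  mr <- fx_mr(); blut <- fx_blut()
  # zero field: identically zero with a zero-width envelope
  f0 <- w$field
  f0$d_hbo2[] <- 0; f0$d_hbr[] <- 0; f0$d_hbt[] <- 0
  p0 <- predict_bold(f0, w$baseline, blut, mr)
  expect_identical(max(abs(p0$central)), 0)
  expect_identical(max(p0$upper - p0$lower), 0)

  # surround signature: Hbr up, HbT down -> negative BOLD during stimulus
  fneg <- f0
  nt <- dim(f0$d_hbt)[1]
  shape <- rep(c(0, 1, 0), c(1, nt - 2, 1))
  fneg$d_hbr <- array(1.5 * shape, dim(f0$d_hbr))
  fneg$d_hbt <- array(-2 * shape, dim(f0$d_hbt))
  fneg$d_hbo2 <- fneg$d_hbt - fneg$d_hbr
  pneg <- predict_bold(fneg, w$baseline, blut, mr)
  expect_lt(max(pneg$central[2, , ]), 0)

  # mid-radius prediction lies inside the envelope everywhere
  pr <- predict_bold(w$field, w$baseline, blut, mr)
  expect_true(all(pr$central >= pr$lower - 1e-12))
  expect_true(all(pr$central <= pr$upper + 1e-12))
  expect_equal(pr$qc$n_saturation_clipped, 0)
})

test_that("the baseline-saturation sweep covers degenerate grids and rejects bad ones", {
  w <- fx_positive_world()
  sw1 <- y0_sweep(w$stack, fx_lut_hom(), w$tissue, fx_optics(), fx_mr(),
                  fx_blut(), w$mask, y0_grid = 0.5)
  expect_equal(sw1$argmax_y0, 0.5)
  expect_equal(nrow(sw1$table), 1)
  expect_error(y0_sweep(w$stack, fx_lut_hom(), w$tissue, fx_optics(),
                        fx_mr(), fx_blut(), w$mask, y0_grid = numeric(0)),
               "non-empty")
  expect_error(y0_sweep(w$stack, fx_lut_hom(), w$tissue, fx_optics(),
                        fx_mr(), fx_blut(), w$mask, y0_grid = c(0.5, 1.2)),
               "0, 1")
})
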