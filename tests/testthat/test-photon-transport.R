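test_that("photon weight is conserved exactly and ballistic media remit nothing", {
  tis <- heterogeneous_tissue()
  for (mua in c(0.05, 0.5, 2)) {
    r <- simulate_photons(tis, mua, n_photons = 20000, seed = 11)
    expect_lt(abs(r$weight_balance - 1), 1e-9)
    expect_false(r$empty)
    # every remitted photon travels at least twice its maximum depth
    expect_equal(r$path_depth_ok_fraction, 1)
  }
  # no scattering: photons never turn back
  r0 <- simulate_photons(tis, 0.1, mus_per_mm = 0, n_photons = 2000,
                         seed = 1)
  expect_true(r0$empty)
  expect_equal(r0$remitted_fraction, 0)
  expect_identical(unname(r0$mean_path_mm), rep(0, 5))
  expect_error(simulate_photons(tis, 0.1, n_photons = 0), ">= 1")
})

test_that("remitted path length shrinks with absorption (paired seeds, 1e5 photons)", {
  tis <- homogeneous_tissue()
  lo <- simulate_photons(tis, 0.05, n_photons = 1e5, seed = 21)
  hi <- simulate_photons(tis, 0.5, n_photons = 1e5, seed = 21)
  expect_gt(lo$mean_total_path_mm, hi$mean_total_path_mm)
})

test_that("mean remitted path matches the diffusion differential-pathlength oracle", {
  # semi-infinite slab, mus' = 1 /mm (mus = 10, g = 0.9), mua = 0.01 /mm
  tis <- homogeneous_tissue(depth_mm = 200)
  mc <- simulate_photons(tis, 0.01, mus_per_mm = 10, g = 0.9,
                         n_photons = 1e5, seed = 7)
  oracle <- diffusion_pathlength_oracle(0.01, 1)
  expect_lt(abs(mc$mean_total_path_mm - oracle) / oracle, 0.15)
})

test_that("homogeneous path lengths are insensitive to layer subdivision", {
  one <- tissue_model(list(tissue_layer(0, 10, 0.06)), "homogeneous")
  two <- tissue_model(list(tissue_layer(0, 5, 0.06),
                           tissue_layer(5, 10, 0.06)), "heterogeneous")
  a <- simulate_photons(one, 0.2, n_photons = 4e4, seed = 31)
  b <- simulate_photons(two, 0.2, n_photons = 4e4, seed = 32)
  tot_a <- sum(a$mean_path_mm)
  tot_b <- sum(b$mean_path_mm)
  se <- sqrt(a$se_total_path_mm^2 + b$se_total_path_mm^2)
  expect_lt(abs(tot_a - tot_b), 2 * se + 1e-6)
})

test_that("lookup tables interpolate exactly at nodes and stay monotone in absorption", {
  lut <- fx_lut_hom()
  g <- lut$mua_grid
  # node identity
  for (b in 1:4)
    expect_equal(as.vector(lookup_pathlength(lut, b, g[3])),
                 as.vector(lut$pathlength_mm[b, 3, ]))
  # midpoint bounded by neighbours
  mid <- (g[4] + g[5]) / 2
  v <- lookup_pathlength(lut, 2, mid)[1, ]
  lo <- lut$pathlength_mm[2, 4, ]; hi <- lut$pathlength_mm[2, 5, ]
  expect_true(all(v >= pmin(lo, hi) - 1e-12 & v <= pmax(lo, hi) + 1e-12))
  # total path non-increasing along the grid (MC jitter allowance)
  for (b in 1:4) {
    tot <- apply(lut$pathlength_mm[b, , , drop = FALSE], 2, sum)
    expect_true(all(diff(tot) < 0.05 * tot[-length(tot)] + 1e-9))
  }
  # no extrapolation
  expect_error(lookup_pathlength(lut, 1, max(g) * 1.01), "outside")
  expect_error(lookup_pathlength(lut, 1, min(g) * 0.5), "outside")
})

test_that("degenerate single-node grids and serialisation round trips work", {
  tis <- homogeneous_tissue()
  lut1 <- build_lut(tis, fx_optics(), mua_grid = 0.3, n_photons = 2000,
                    seed = 4)
  expect_equal(dim(lut1$pathlength_mm), c(4, 1, 1))
  expect_equal(as.vector(lookup_pathlength(lut1, 3, 0.3)),
               as.vector(lut1$pathlength_mm[3, 1, ]))
  expect_error(build_lut(tis, fx_optics(), mua_grid = c(0.3, 0.2)),
               "increasing")

  f <- withr::local_tempfile(fileext = ".json")
  save_plut(fx_lut_hom(), f)
  back <- load_plut(f)
  expect_equal(back$n_photons, fx_lut_hom()$n_photons)
  expect_equal(back$seed, fx_lut_hom()$seed)
  expect_equal(back$tissue_hash, fx_lut_hom()$tissue_hash)
  expect_equal(back$pathlength_mm, fx_lut_hom()$pathlength_mm,
               tolerance = 1e-12)
})

test_that("off-grid lookups agree with direct simulation within Monte Carlo error", {
  lut <- fx_lut_hom()
  mua <- 0.45   # between the 0.35 and 0.6 nodes
  direct <- simulate_photons(homogeneous_tissue(), mua, n_photons = 4e4,
                             seed = 99)
  interp <- sum(lookup_pathlength(lut, 1, mua))
  # combine the direct-run SE with the (larger-n) node SEs
  expect_lt(abs(interp - direct$mean_total_path_mm),
            3 * direct$se_total_path_mm + 0.05 * direct$mean_total_path_mm)
})
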