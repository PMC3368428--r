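test_that("the design matrix has boxcar, ramp and DC columns with the paradigm timing", {
  p <- make_paradigm()
  X <- build_design(p, 1)
  expect_equal(ncol(X), 3)
  expect_equal(colnames(X), c("response", "ramp", "dc"))
  expect_identical(unname(X[1:60, "response"]), rep(0, 60))
  expect_equal(sum(X[, "dc"]), nrow(X))
  expect_equal(range(X[, "ramp"]), c(0, 1))
  expect_true(all(diff(X[, "ramp"]) > 0))
  # 16 active frames per trial at 1 Hz
  expect_equal(sum(X[, "response"]), 16 * 30)
  expect_error(build_design(p, 1, duration_s = 1), "representable")
})

test_that("exact linear inputs are fitted exactly and flagged as zero-residual", {
  p <- make_paradigm(n_trials = 2)
  X <- build_design(p, 1, duration_s = 60 + 2 * 70)
  y <- 2 * X[, "ramp"] + 3
  g <- fit_glm(y, X)
  expect_equal(unname(g$beta[, 1]), c(0, 2, 3), tolerance = 1e-10)
  expect_true(g$zero_residual[1])
  expect_equal(abs(g$z[1]), 0)   # zero response beta on a zero-residual voxel
  y2 <- 5 * X[, "response"] + X[, "ramp"]
  g2 <- fit_glm(y2, X)
  expect_true(g2$zero_residual[1])
  expect_equal(g2$z[1], 1e6)
  expect_error(fit_glm(y, cbind(X, X[, 1])), "rank")
})

test_that("betas match a normal-equations oracle on 100 random small problems", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    n <- sample(10:30, 1)
    X <- cbind(rnorm(n), seq_len(n) / n, 1)
    y <- rnorm(n)
    b_pkg <- fit_glm(y, X)$beta[, 1]
    b_orc <- as.vector(ols_oracle(X, y))
    worst <- max(worst, max(abs(b_pkg - b_orc)) / max(abs(b_orc), 1))
  }
  expect_lt(worst, 1e-10)
})

test_that("z grows like the square root of the series length", {
  p <- make_paradigm(baseline_s = 20, n_trials = 8, isi_s = 40,
                     stim_duration_s = 16, ois_trial_window_s = 30,
                     ois_prestim_s = 2)
  X1 <- build_design(p, 1, duration_s = 20 + 8 * 40)
  p2 <- make_paradigm(baseline_s = 20, n_trials = 16, isi_s = 40,
                      stim_duration_s = 16, ois_trial_window_s = 30,
                      ois_prestim_s = 2)
  X2 <- build_design(p2, 1, duration_s = 20 + 16 * 40)
  set.seed(7)
  reps <- 40
  z1 <- z2 <- numeric(reps)
  for (i in seq_len(reps)) {
    z1[i] <- fit_glm(X1[, 1] + rnorm(nrow(X1)), X1)$z[1]
    z2[i] <- fit_glm(X2[, 1] + rnorm(nrow(X2)), X2)$z[1]
  }
  ratio <- mean(z2) / mean(z1)
  expect_lt(abs(ratio - sqrt(2)), 0.2 * sqrt(2))
})

test_that("cluster thresholding enforces size and sign rules exhaustively", {
  z <- matrix(0, 12, 12)
  m0 <- threshold_clusters(z)
  expect_false(any(m0$positive) || any(m0$negative))

  # a 4-voxel component at z = 10 is excluded by the size >= 6 rule
  z4 <- z; z4[2:3, 2:3] <- 10
  expect_false(any(threshold_clusters(z4)$positive))
  # a 6-voxel component at z = -3 is retained in the negative mask
  z6 <- z; z6[5:10, 7] <- -3
  m6 <- threshold_clusters(z6)
  expect_equal(sum(m6$negative), 6)
  expect_false(any(m6$positive))

  # exhaustive property on random maps: every retained component >= size,
  # masks disjoint, and connectivity respected
  set.seed(33)
  for (i in 1:20) {
    zr <- matrix(rnorm(15 * 15, sd = 3), 15, 15)
    for (conn in c(4, 8)) {
      m <- threshold_clusters(zr, z_pos = 3, z_neg = -3, min_cluster = 4,
                              connectivity = conn)
      expect_false(any(m$positive & m$negative))
      for (msk in m) {
        lab <- oisbold:::label_components(msk, conn)
        if (any(msk))
          expect_true(all(tabulate(lab[lab > 0]) >= 4))
      }
    }
  }
  expect_error(threshold_clusters(z, z_pos = -1), "z_pos")
})

test_that("region time series extraction, folding and commutation are exact", {
  p <- make_paradigm(n_trials = 3)
  nt <- round((60 + 3 * 70) * 1)
  set.seed(5)
  series <- array(rnorm(nt * 4 * 4), dim = c(nt, 4, 4))
  mask1 <- matrix(FALSE, 4, 4); mask1[2, 3] <- TRUE
  expect_identical(region_timeseries(series, mask1), series[, 2, 3])

  cmask <- matrix(TRUE, 4, 4)
  const <- array(7, dim = c(nt, 4, 4))
  expect_identical(unique(region_timeseries(const, cmask)), 7)

  folded <- region_timeseries(series, cmask, fold = TRUE, paradigm = p,
                              rate_hz = 1)
  expect_length(folded, 70)
  # fold(mean over mask) == mean over mask(fold)
  fold_first <- fold_trials(series, p, rate_hz = 1)
  expect_equal(as.vector(folded),
               as.vector(apply(fold_first, 1, mean)), tolerance = 1e-12)
  expect_error(region_timeseries(series, matrix(FALSE, 4, 4)), "empty")
})

test_that("design refinement fixes the response column and improves its fit", {
  p <- make_paradigm(n_trials = 2)
  X <- build_design(p, 1, duration_s = 60 + 2 * 70)
  # refining with (a scaled copy of) the boxcar reproduces it up to scale
  Xr <- refine_design(X, 3 * X[, "response"])
  resp <- X[, "response"] - mean(X[, "response"])
  expect_gt(abs(cor(Xr[, "response"], X[, "response"])), 0.98)

  # fitting the very series used for refinement cannot lower the response z
  set.seed(11)
  shape <- stats::filter(X[, "response"], rep(1 / 6, 6), sides = 1)
  shape[is.na(shape)] <- 0
  y <- as.vector(shape) + rnorm(nrow(X), sd = 0.3)
  z_box <- abs(fit_glm(y, X)$z[1])
  Xr2 <- refine_design(X, y)
  z_ref <- abs(fit_glm(y, Xr2)$z[1])
  expect_gte(z_ref, z_box)
  expect_error(refine_design(X, rep(2, nrow(X))), "zero-variance")
  expect_error(refine_design(X, 1:5), "length")
})
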