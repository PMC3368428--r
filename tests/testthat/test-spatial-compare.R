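test_that("Gaussian smoothing preserves constants and matches the closed-form kernel", {
  const <- matrix(4.2, 20, 20)
  expect_lt(max(abs(smooth_map(const, 489, 469) - 4.2)), 1e-12)

  # unit impulse: response equals the normalised sampled Gaussian
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- smooth_map(imp, 489, 469)
  expect_lt(abs(sum(sm) - 1), 1e-6)     # discrete kernel sums to one
  sig <- 489 / 469
  r <- ceiling(4 * sig)
  k1 <- exp(-((-r):r)^2 / (2 * sig^2)); k1 <- k1 / sum(k1)
  closed <- outer(k1, k1)
  got <- sm[(21 - r):(21 + r), (21 - r):(21 + r)]
  expect_lt(max(abs(got - closed)), 1e-6)
  expect_identical(smooth_map(const, 0, 469), const)
})

test_that("cubic subsampling honours the dimension contract and beats bilinear on smooth surfaces", {
  m <- matrix(rnorm(200 * 200), 200, 200)
  expect_equal(dim(subsample_map(m, 0.15)), c(30, 30))
  expect_lt(max(abs(subsample_map(m, 1) - m)), 1e-12)
  expect_error(subsample_map(m, 0.005), "smaller")
  expect_error(subsample_map(m, 1.5), "scale")

  # quadratic surface: Keys cubic reproduces it better than bilinear
  x <- seq(0, 1, length.out = 80)
  quad <- outer(x, x, function(a, b) 2 + a^2 + 0.5 * b^2 + a * b)
  down_c <- subsample_map(quad, 0.4, method = "cubic")
  down_b <- subsample_map(quad, 0.4, method = "bilinear")
  xt <- ((seq_len(32) - 0.5) / 0.4 - 0.5) / 79  # target coords on [0,1]
  truth <- outer(xt, xt, function(a, b) 2 + a^2 + 0.5 * b^2 + a * b)
  inner <- 3:30   # edge taps are clamped; compare the interior
  err_c <- max(abs(down_c - truth)[inner, inner])
  err_b <- max(abs(down_b - truth)[inner, inner])
  expect_lt(err_c, err_b)
})

test_that("template matching finds exact crops and recovers synthetic transforms", {
  set.seed(19)
  target <- matrix(rnorm(60 * 60), 60, 60)
  target <- smooth_map(target, 2, 1)
  crop <- target[11:30, 16:35]
  m <- match_template(crop, target, scale_grid = c(0.8, 1), angle_grid = 0)
  expect_equal(m$scale, 1)
  expect_equal(m$ty_px, 10)
  expect_equal(m$tx_px, 15)
  expect_gt(m$correlation, 0.999)

  # anti-correlated template: NCC at the same offset is exactly -1
  cc <- oisbold:::.ncc_offsets_cpp(target, -crop,
                                   matrix(1, nrow(crop), ncol(crop)))
  expect_equal(cc[11, 16], -1, tolerance = 1e-9)

  # known (scale 0.5, 10 deg) transform, noisy target, recovered within
  # one grid step
  templ <- smooth_map(matrix(rnorm(80 * 80), 80, 80), 3, 1)
  s <- 0.5; th <- 10 * pi / 180
  oy <- round(80 * s); ox <- round(80 * s)
  gy <- matrix(seq_len(oy) - 1 - (oy - 1) / 2, oy, ox)
  gx <- matrix(seq_len(ox) - 1 - (ox - 1) / 2, oy, ox, byrow = TRUE)
  sy <- (cos(th) * gy - sin(th) * gx) / s + (80 - 1) / 2
  sx <- (sin(th) * gy + cos(th) * gx) / s + (80 - 1) / 2
  small <- matrix(oisbold:::bilinear_sample(templ, as.vector(sy),
                                            as.vector(sx)), oy, ox)
  small[is.na(small)] <- 0
  big <- matrix(0, 70, 70)
  big[21:(20 + oy), 26:(25 + ox)] <- small
  set.seed(4)
  big <- big + matrix(rnorm(70 * 70, sd = sd(small) / 10), 70, 70)
  rec <- match_template(templ, big, scale_grid = seq(0.4, 0.6, 0.05),
                        angle_grid = seq(0, 20, 5))
  expect_lt(abs(rec$scale - 0.5), 0.05 + 1e-9)
  expect_lt(abs(rec$angle_deg - 10), 5 + 1e-9)
  expect_lt(abs(rec$ty_px - 20), 2)
  expect_lt(abs(rec$tx_px - 25), 2)

  expect_error(match_template(matrix(1, 5, 5), target), "zero-variance")
})

test_that("normalised correlation is invariant to affine intensity rescaling", {
  set.seed(23)
  target <- smooth_map(matrix(rnorm(40 * 40), 40, 40), 1.5, 1)
  templ <- target[6:20, 9:23]
  base <- match_template(templ, target, scale_grid = 1, angle_grid = 0)
  resc <- match_template(2.5 * templ + 7, 0.3 * target - 2,
                         scale_grid = 1, angle_grid = 0)
  expect_equal(base$correlation, resc$correlation, tolerance = 1e-9)
  expect_equal(c(base$ty_px, base$tx_px), c(resc$ty_px, resc$tx_px))
})

test_that("projective fits are exact for four pairs and match the oracle for more", {
  id <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  h_id <- fit_projective_transform(id, id)
  expect_lt(max(abs(h_id$H - diag(3))), 1e-9)
  expect_lt(h_id$rms_px, 1e-9)

  set.seed(3)
  src <- cbind(c(0, 20, 22, 1), c(0, 1, 21, 19))
  H_true <- matrix(c(1.1, 0.1, 3, -0.05, 0.9, -2, 1e-3, -5e-4, 1), 3, 3,
                   byrow = TRUE)
  dst <- apply_homography(H_true, src)
  fit4 <- fit_projective_transform(src, dst)
  expect_lt(max(abs(apply_homography(fit4, src) - dst)), 1e-9)

  src8 <- cbind(runif(8, 0, 30), runif(8, 0, 30))
  dst8 <- apply_homography(H_true, src8) + matrix(rnorm(16, sd = 0.2), 8)
  fit8 <- fit_projective_transform(src8, dst8)
  H_orc <- homography_oracle(src8, dst8)
  expect_lt(max(abs(fit8$H - H_orc)), 1e-8)

  expect_error(fit_projective_transform(src[1:3, ], dst[1:3, ]), "4 point")
  coll <- cbind(0:3, 0:3)
  expect_error(fit_projective_transform(coll, coll), "degenerate")
})

test_that("homographies compose and warps invert within interpolation loss", {
  set.seed(9)
  img <- smooth_map(matrix(rnorm(50 * 50), 50, 50), 3.5, 1)

  # identity and integer translation are exact
  expect_equal(warp_image(img, diag(3)), img, tolerance = 1e-12)
  Ht <- diag(3); Ht[1, 3] <- 4; Ht[2, 3] <- -3   # x + 4, y - 3
  w <- warp_image(img, Ht, fill = 0)
  expect_equal(w[10, 20], img[13, 16], tolerance = 1e-12)

  # warp then inverse-warp: error bounded by interpolation loss
  Hs <- matrix(c(0.95, 0.08, 3, -0.06, 1.02, 2, 2e-4, -1e-4, 1), 3, 3,
               byrow = TRUE)
  fwd <- warp_image(img, Hs, fill = NA)
  back <- warp_image(fwd, solve(Hs), fill = NA)
  ok <- !is.na(back) & !is.na(img)
  ok[c(1:3, 48:50), ] <- FALSE; ok[, c(1:3, 48:50)] <- FALSE
  rng <- diff(range(img))
  expect_lt(max(abs(back[ok] - img[ok])), 0.02 * rng)

  # composition: fit(src->mid) then fit(mid->dst) equals fit(src->dst)
  src <- cbind(c(0, 30, 28, 2, 15), c(1, 0, 29, 27, 14))
  H1 <- matrix(c(1.05, 0.02, 1, -0.01, 0.97, 2, 1e-4, 2e-4, 1), 3, 3,
               byrow = TRUE)
  H2 <- matrix(c(0.98, -0.03, -2, 0.02, 1.06, 1, -2e-4, 1e-4, 1), 3, 3,
               byrow = TRUE)
  mid <- apply_homography(H1, src)
  dst <- apply_homography(H2, mid)
  f1 <- fit_projective_transform(src, mid)
  f2 <- fit_projective_transform(mid, dst)
  f12 <- fit_projective_transform(src, dst)
  via <- apply_homography(f2, apply_homography(f1, src))
  direct <- apply_homography(f12, src)
  expect_lt(max(abs(via - direct)), 1e-6)

  expect_error(warp_image(img, matrix(0, 3, 3)), "singular")
})
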