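# Independent oracles, coded without reference to the package internals.

# Differential path length of diffusely remitted light from a semi-infinite
# medium, from steady-state diffusion theory with an extrapolated boundary:
# plane isotropic source at one transport mean free path, matched surface.
# R(mua) = (1/2) [exp(-mueff z0) + exp(-mueff (z0 + 2 zb))]; the mean photon
# path length is -d ln R / d mua.
diffusion_pathlength_oracle <- function(mua, musp) {
  refl <- function(m) {
    mut <- m + musp
    z0 <- 1 / mut
    D <- 1 / (3 * mut)
    zb <- 2 * D
    mueff <- sqrt(m / D)
    0.5 * (exp(-mueff * z0) + exp(-mueff * (z0 + 2 * zb)))
  }
  h <- mua * 1e-4
  -(log(refl(mua + h)) - log(refl(mua - h))) / (2 * h)
}

# Static-dephasing oracle: numerical average of exp(i phi(TE)) over random
# cylinder orientations and positions with NO diffusion, paired between the
# perturbed and baseline saturations within each geometry.
static_dephasing_oracle <- function(V, Y, r_um, mr, v0 = 0.06, y0 = 0.5,
                                    n_geom = 12, n_pos = 15000, seed = 11) {
  set.seed(seed)
  pref <- function(omy)
    2 * pi * mr$gamma_rad_per_s_per_T * mr$b0_T * mr$dchi0_ppm_cgs * 1e-6 *
    mr$hct * omy
  n_cyl <- mr$n_cylinders
  vals <- numeric(n_geom)
  for (g in seq_len(n_geom)) {
    L <- r_um * sqrt(n_cyl * pi / V)
    ax <- matrix(runif(n_cyl * 3), ncol = 3) * L
    ct <- 2 * runif(n_cyl) - 1
    ph <- 2 * pi * runif(n_cyl)
    st <- sqrt(pmax(0, 1 - ct^2))
    u <- cbind(st * cos(ph), st * sin(ph), ct)
    P <- matrix(runif(n_pos * 3), ncol = 3) * L
    phi <- numeric(n_pos)
    inside <- rep(FALSE, n_pos)
    for (k in seq_len(n_cyl)) {
      d <- sweep(P, 2, ax[k, ])
      d <- d - L * round(d / L)
      tt <- as.vector(d %*% u[k, ])
      e <- d - outer(tt, u[k, ])
      rho2 <- rowSums(e^2)
      inside <- inside | rho2 < r_um^2
      s2 <- 1 - u[k, 3]^2
      b <- c(-u[k, 3] * u[k, 1], -u[k, 3] * u[k, 2], 1 - u[k, 3]^2)
      bn2 <- sum(b^2)
      c2 <- if (bn2 > 1e-24)
        2 * as.vector(e %*% b)^2 / (rho2 * bn2) - 1 else rep(0, n_pos)
      phi <- phi + (r_um^2 / rho2) * s2 * c2
    }
    phi <- phi[!inside] * mr$te_s
    r2 <- function(p) -log(Mod(mean(exp(1i * p * phi)))) / mr$te_s
    vals[g] <- r2(pref(1 - Y)) - r2(pref(1 - y0))
  }
  list(mean = mean(vals), se = sd(vals) / sqrt(n_geom))
}

# brute-force least squares via explicit normal equations
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# projective transform by explicit normal equations on the DLT system
homography_oracle <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 8)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(t(A) %*% A, t(A) %*% b)
  rbind(matrix(h[1:6], 2, 3, byrow = TRUE), c(h[7], h[8], 1))
}
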