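#' Forward-render a four-wavelength attenuation stack
#'
#' Maps a haemodynamic field to the attenuation changes
#' `A(band, t, y, x) = -ln(I/I0)` the imaging system would record, using
#' the same Beer-Lambert/path-length model the inversion assumes:
#' `A = sum_layer L_layer(band, mua_layer) * dmua_layer`, with the photon
#' path lengths read from the Monte Carlo lookup table at the perturbed
#' absorption.  Each region's concentration change is distributed over the
#' tissue layers according to its depth profile (superficial 0-1 mm for the
#' activated region, deep 1-2 mm for the surround, by default); pixels
#' outside any region carry no change.  Optional Gaussian measurement noise
#' is added in the attenuation (log) domain, mirroring where the inversion
#' operates.
#'
#' @param field an [generate_haemodynamics()] field (uM changes).
#' @param tissue the [tissue_model()] the stack is rendered with (the
#'   "true" tissue).
#' @param lut a [build_lut()] table for `tissue` and the same bands.
#' @param optics an [optical_constants()] object.
#' @param noise_sd Gaussian noise s.d. in attenuation units (0 = noise
#'   free).
#' @param seed integer seed for the noise.
#' @param baseline optional [baseline_concentrations()] override; default
#'   computed from `tissue` and `optics`.
#' @return An `ois_stack`: attenuation array `[band, time, y, x]`,
#'   `wavelengths_nm`, `rate_hz`, `pixel_um`.
#' @export
render_wavelength_stack <- function(field, tissue, lut, optics,
                                    noise_sd = 0, seed = 1,
                                    baseline = NULL) {
  stopifnot(inherits(field, "ois_field"), inherits(tissue, "tissue_model"),
            inherits(lut, "ois_plut"), inherits(optics, "ois_optics"))
  if (lut$n_layers != n_layers(tissue))
    stop("LuT layer count does not match the tissue model")
  if (is.null(baseline)) baseline <- baseline_concentrations(tissue, optics)
  nb <- length(optics$bands_nm)
  nt <- dim(field$d_hbt)[1]; ny <- dim(field$d_hbt)[2]; nx <- dim(field$d_hbt)[3]
  nl <- n_layers(tissue)

  # per-pixel, per-layer depth weights from the region bookkeeping
  W <- array(0, dim = c(nl, ny, nx))
  uniform_w <- depth_profile_weights(tissue, "uniform")
  for (l in seq_len(nl)) W[l, , ] <- uniform_w[l]
  if (!is.null(field$regions) && !is.null(field$region_id)) {
    for (ri in seq_along(field$regions)) {
      wr <- depth_profile_weights(tissue, field$regions[[ri]]$depth)
      sel <- field$region_id == ri
      for (l in seq_len(nl)) {
        plane <- W[l, , ]
        plane[sel] <- wr[l]
        W[l, , ] <- plane
      }
    }
  }

  A <- array(0, dim = c(nb, nt, ny, nx))
  do <- matrix(field$d_hbo2, nt, ny * nx)
  dr <- matrix(field$d_hbr, nt, ny * nx)
  for (b in seq_len(nb)) {
    delta_mua_px <- optics$eps_hbo2[b] * do + optics$eps_hbr[b] * dr  # nt x npx
    acc <- matrix(0, nt, ny * nx)
    for (l in seq_len(nl)) {
      wl <- rep(as.vector(W[l, , ]), each = nt)
      dmua_l <- delta_mua_px * wl
      mua_l <- baseline$mua0[b, l] + dmua_l
      rng <- range(mua_l)
      g <- lut$mua_grid
      if (rng[1] < g[1] || rng[2] > g[length(g)]) {
        bad <- which(mua_l < g[1] | mua_l > g[length(g)])[1]
        px <- (bad - 1) %/% nt + 1
        stop(sprintf(
          "absorption %.4g /mm outside LuT range at band %g nm, layer %d, pixel %d (y=%d, x=%d)",
          mua_l[bad], optics$bands_nm[b], l, px,
          (px - 1) %% ny + 1, (px - 1) %/% ny + 1))
      }
      L <- matrix(lookup_pathlength(lut, b, as.vector(mua_l))[, l], nt)
      acc <- acc + L * dmua_l
    }
    A[b, , , ] <- array(acc, dim = c(nt, ny, nx))
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    A <- A + array(rnorm(length(A), sd = noise_sd), dim(A))
  }
  structure(list(attenuation = A, wavelengths_nm = optics$bands_nm,
                 halfwidth_nm = optics$halfwidth_nm,
                 rate_hz = field$rate_hz, pixel_um = field$pixel_um),
            class = "ois_stack")
}

#' @export
print.ois_stack <- function(x, ...) {
  d <- dim(x$attenuation)
  cat(sprintf(
    "Attenuation stack: %d bands (%s nm), %d frames @ %g Hz, %d x %d px\n",
    d[1], paste(x$wavelengths_nm, collapse = "/"), d[2], x$rate_hz,
    d[3], d[4]))
  invisible(x)
}
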