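#' Region specification for synthetic haemodynamic responses
#'
#' Describes one circular cortical region and the trial-locked haemodynamic
#' response placed in it.  A positive-polarity region carries the signature
#' of functional activation (total haemoglobin up, deoxy-haemoglobin down,
#' with an optional early "deoxy dip" and post-stimulus overshoot); a
#' negative-polarity region carries the inverted signature observed in
#' cortex surrounding an activated area (HbT down, Hbr up).
#'
#' @param center_px integer-ish `(y, x)` disc centre in pixels.
#' @param radius_px disc radius in pixels.
#' @param polarity `"positive"` or `"negative"`.
#' @param hbt_peak_uM,hbr_peak_uM peak concentration changes (uM); their
#'   signs must match the polarity (positive: HbT > 0 > Hbr; negative:
#'   HbT < 0 < Hbr).
#' @param peak_time_s time-to-peak of the response after stimulus onset.
#' @param plateau_fraction sustained plateau level as a fraction of peak.
#' @param dip_amplitude_uM amplitude of an early Hbr lobe of sign opposite
#'   to `hbr_peak_uM` (the capillary "deoxy dip"); 0 disables it.
#' @param overshoot_amplitude_uM amplitude of a post-stimulus Hbr lobe of
#'   sign opposite to baseline (an Hbr undershoot maps to the ~1% BOLD
#'   overshoot); 0 disables it.
#' @param depth depth placement of the change used by the forward optical
#'   model: `"superficial"` (0-1 mm), `"deep"` (1-2 mm), `"uniform"`, or an
#'   explicit per-layer weight vector.
#' @return A `region_spec` object.
#' @export
region_spec <- function(center_px, radius_px,
                        polarity = c("positive", "negative"),
                        hbt_peak_uM, hbr_peak_uM,
                        peak_time_s = 4, plateau_fraction = 0.5,
                        dip_amplitude_uM = 0, overshoot_amplitude_uM = 0,
                        depth = "superficial") {
  polarity <- match.arg(polarity)
  if (polarity == "positive" && !(hbt_peak_uM > 0 && hbr_peak_uM < 0))
    stop("positive region requires hbt_peak_uM > 0 and hbr_peak_uM < 0")
  if (polarity == "negative" && !(hbt_peak_uM < 0 && hbr_peak_uM > 0))
    stop("negative region requires hbt_peak_uM < 0 and hbr_peak_uM > 0")
  if (radius_px <= 0) stop("radius_px must be positive")
  structure(list(center_px = center_px, radius_px = radius_px,
                 polarity = polarity, hbt_peak_uM = hbt_peak_uM,
                 hbr_peak_uM = hbr_peak_uM, peak_time_s = peak_time_s,
                 plateau_fraction = plateau_fraction,
                 dip_amplitude_uM = dip_amplitude_uM,
                 overshoot_amplitude_uM = overshoot_amplitude_uM,
                 depth = depth), class = "region_spec")
}

#' @rdname region_spec
#' @export
positive_region <- function() {
  region_spec(center_px = c(22, 22), radius_px = 12, polarity = "positive",
              hbt_peak_uM = 5, hbr_peak_uM = -3, peak_time_s = 4,
              plateau_fraction = 0.45, dip_amplitude_uM = 0.3,
              overshoot_amplitude_uM = 0.5, depth = "superficial")
}

#' @rdname region_spec
#' @export
negative_region <- function() {
  region_spec(center_px = c(44, 44), radius_px = 14, polarity = "negative",
              hbt_peak_uM = -2.5, hbr_peak_uM = 1.5, peak_time_s = 8,
              plateau_fraction = 0.6, dip_amplitude_uM = 0,
              overshoot_amplitude_uM = 0.3, depth = "deep")
}

# gamma-variate lobe, unit peak at t = tp (t in seconds, t <= 0 -> 0)
gamma_lobe <- function(t, tp, shape = 8) {
  out <- numeric(length(t))
  pos <- t > 0
  x <- t[pos] / tp
  out[pos] <- x^shape * exp(shape * (1 - x))
  out
}

# trial-locked temporal response shape, unit peak: boxcar convolved with a
# gamma kernel, modulated by an exponential adaptation towards the plateau
trial_response_shape <- function(t_rel, stim_s, peak_time_s,
                                 plateau_fraction, rate_hz) {
  dt <- 1 / rate_hz
  kt <- seq(0, 4 * peak_time_s, by = dt)
  k <- gamma_lobe(kt + dt / 2, peak_time_s / 2, shape = 4)
  k <- k / sum(k)
  box <- as.numeric(t_rel >= 0 & t_rel < stim_s)
  r <- convolve(box, rev(k), type = "open")[seq_along(box)]
  adapt <- plateau_fraction + (1 - plateau_fraction) *
    exp(-pmax(0, t_rel - peak_time_s) / 6)
  s <- r * adapt
  m <- max(s)
  if (m > 0) s / m else s
}

#' Generate a ground-truth haemodynamic field
#'
#' Places smooth, trial-locked gamma-kernel responses in each region of a
#' pixel grid and returns micromolar concentration changes of oxy-, deoxy-
#' and total haemoglobin over time.  HbT and Hbr are generated and HbO2 is
#' their difference, so the closure `d_hbt = d_hbo2 + d_hbr` holds exactly.
#' Outside all regions the field is identically zero (regions have a
#' 1-pixel-sigma Gaussian edge taper, truncated 4 px beyond the radius).
#'
#' @param paradigm an [make_paradigm()] object.
#' @param regions list of [region_spec()]s; must be pairwise non-overlapping
#'   (including taper margin).  Defaults to one positive and one negative
#'   region.
#' @param grid_px `(ny, nx)` grid size in pixels; every region must fit.
#' @param pixel_um pixel size (default 80 um).
#' @param rate_hz sampling rate; default the paradigm's OIS rate.
#' @param duration_s length of the generated series; default the full
#'   paradigm duration.
#' @param noise_uM per-frame i.i.d. Gaussian concentration noise added to
#'   HbT and Hbr (0 = noise-free ground truth).
#' @param seed integer seed (used only when `noise_uM > 0`).
#' @return An `ois_field` object: arrays `d_hbo2`, `d_hbr`, `d_hbt` of
#'   dimension `[time, y, x]` (uM), `time_s`, `rate_hz`, `pixel_um`, region
#'   masks, and the per-pixel depth-profile bookkeeping used by the forward
#'   optical model.
#' @export
generate_haemodynamics <- function(paradigm,
                                   regions = list(positive_region(),
                                                  negative_region()),
                                   grid_px = c(64, 64), pixel_um = 80,
                                   rate_hz = paradigm$ois_rate_hz,
                                   duration_s = paradigm_duration_s(paradigm),
                                   noise_uM = 0, seed = 1) {
  stopifnot(inherits(paradigm, "ois_paradigm"))
  grid_px <- rep_len(as.integer(grid_px), 2L)
  taper_margin <- 4
  if (length(regions) > 1) {
    for (i in seq_along(regions)[-1]) for (j in seq_len(i - 1)) {
      d <- sqrt(sum((regions[[i]]$center_px - regions[[j]]$center_px)^2))
      if (d < regions[[i]]$radius_px + regions[[j]]$radius_px + taper_margin)
        stop("regions overlap (including edge taper)")
    }
  }
  for (r in regions)
    if (any(r$center_px - r$radius_px < 1) ||
        any(r$center_px + r$radius_px > grid_px))
      stop("region extends beyond the grid")

  nt <- round(duration_s * rate_hz)
  time_s <- (seq_len(nt) - 1) / rate_hz
  ny <- grid_px[1]; nx <- grid_px[2]
  d_hbt <- array(0, dim = c(nt, ny, nx))
  d_hbr <- array(0, dim = c(nt, ny, nx))
  region_id <- matrix(0L, ny, nx)
  masks <- list()

  onsets <- onset_times(paradigm)
  for (ri in seq_along(regions)) {
    r <- regions[[ri]]
    # temporal traces, summed over trials (responses are trial-locked)
    hbt_t <- numeric(nt); hbr_t <- numeric(nt)
    for (on in onsets) {
      trel <- time_s - on
      sel <- trel >= 0 & trel < paradigm$isi_s
      if (!any(sel)) next
      s <- trial_response_shape(trel[sel], paradigm$stim_duration_s,
                                r$peak_time_s, r$plateau_fraction, rate_hz)
      hbt_t[sel] <- hbt_t[sel] + r$hbt_peak_uM * s
      hbr_t[sel] <- hbr_t[sel] + r$hbr_peak_uM * s
      if (r$dip_amplitude_uM > 0)
        hbr_t[sel] <- hbr_t[sel] - sign(r$hbr_peak_uM) * r$dip_amplitude_uM *
          gamma_lobe(trel[sel], 1.5, shape = 6)
      if (r$overshoot_amplitude_uM > 0)
        hbr_t[sel] <- hbr_t[sel] - r$overshoot_amplitude_uM *
          gamma_lobe(trel[sel] - paradigm$stim_duration_s, 6, shape = 6)
    }
    # spatial mask: disc with Gaussian edge taper (sigma = 1 px)
    dy <- matrix(seq_len(ny) - r$center_px[1], ny, nx)
    dx <- matrix(seq_len(nx) - r$center_px[2], ny, nx, byrow = TRUE)
    dist <- sqrt(dy^2 + dx^2)
    m <- exp(-pmax(0, dist - r$radius_px)^2 / 2)
    m[dist > r$radius_px + taper_margin] <- 0
    masks[[ri]] <- dist <= r$radius_px
    region_id[masks[[ri]]] <- ri
    idx <- which(m > 0)
    for (k in idx) {
      yy <- ((k - 1) %% ny) + 1
      xx <- ((k - 1) %/% ny) + 1
      d_hbt[, yy, xx] <- d_hbt[, yy, xx] + hbt_t * m[k]
      d_hbr[, yy, xx] <- d_hbr[, yy, xx] + hbr_t * m[k]
    }
  }

  if (noise_uM > 0) {
    set.seed(as.integer(seed))
    d_hbt <- d_hbt + array(rnorm(length(d_hbt), sd = noise_uM), dim(d_hbt))
    d_hbr <- d_hbr + array(rnorm(length(d_hbr), sd = noise_uM), dim(d_hbr))
  }

  # define HbO2 = HbT - Hbr once, then rebuild HbT as the exact sum so the
  # closure d_hbt == d_hbo2 + d_hbr holds bit-exactly
  d_hbo2 <- d_hbt - d_hbr
  d_hbt <- d_hbo2 + d_hbr
  structure(list(
    d_hbo2 = d_hbo2, d_hbr = d_hbr, d_hbt = d_hbt,
    time_s = time_s, rate_hz = rate_hz, pixel_um = pixel_um,
    grid_px = grid_px, regions = regions, region_masks = masks,
    region_id = region_id), class = "ois_field")
}

#' @export
print.ois_field <- function(x, ...) {
  cat(sprintf("Haemodynamic field: %d frames @ %g Hz, %d x %d px (%g um)\n",
              dim(x$d_hbt)[1], x$rate_hz, x$grid_px[1], x$grid_px[2],
              x$pixel_um))
  cat(sprintf("  %d region(s); max |dHbT| %.3g uM\n",
              length(x$regions), max(abs(x$d_hbt))))
  invisible(x)
}
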