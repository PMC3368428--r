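#' Configuration of the MR signal attenuation Monte Carlo
#'
#' Physical constants and simulation sizes for the extravascular
#' gradient-echo dephasing simulation: 7 T field, TE = 12 ms, water
#' diffusion coefficient 1e-9 m^2/s, a susceptibility difference of 0.18 ppm
#' (cgs) per unit haematocrit between fully deoxygenated and fully
#' oxygenated blood at haematocrit 0.4, and a mean vessel radius bracketed
#' between 3 and 20 um.
#'
#' @param b0_T main field (T).
#' @param te_s echo time (s); must be an integer multiple of `dt_s`.
#' @param gamma_rad_per_s_per_T proton gyromagnetic ratio.
#' @param d_water_m2_per_s water diffusion coefficient.
#' @param dchi0_ppm_cgs deoxy-oxy susceptibility difference per unit Hct
#'   (ppm, cgs convention).
#' @param hct haematocrit.
#' @param radius_um_range vessel radius envelope `[low, high]` (um).
#' @param n_protons protons per simulated state.
#' @param dt_s random-walk time step (s).
#' @param n_cylinders cylinders per periodic voxel.
#' @param n_geom independent geometry realisations averaged per state.
#' @param seed base integer seed.
#' @return An `mr_config` list.
#' @export
mr_config <- function(b0_T = 7, te_s = 0.012,
                      gamma_rad_per_s_per_T = 2.675e8,
                      d_water_m2_per_s = 1e-9, dchi0_ppm_cgs = 0.18,
                      hct = 0.4, radius_um_range = c(3, 20),
                      n_protons = 10000, dt_s = 2e-4,
                      n_cylinders = 16, n_geom = 2, seed = 1) {
  if (any(c(b0_T, te_s, gamma_rad_per_s_per_T, d_water_m2_per_s,
            dchi0_ppm_cgs, hct, dt_s) <= 0))
    stop("physical constants must be positive")
  steps <- te_s / dt_s
  if (abs(steps - round(steps)) > 1e-9)
    stop("te_s must be an integer multiple of dt_s")
  if (radius_um_range[1] >= radius_um_range[2])
    stop("radius range must be increasing")
  structure(list(b0_T = b0_T, te_s = te_s,
                 gamma_rad_per_s_per_T = gamma_rad_per_s_per_T,
                 d_water_m2_per_s = d_water_m2_per_s,
                 dchi0_ppm_cgs = dchi0_ppm_cgs, hct = hct,
                 radius_um_range = radius_um_range,
                 n_protons = as.integer(n_protons), dt_s = dt_s,
                 n_cylinders = as.integer(n_cylinders),
                 n_geom = as.integer(n_geom), seed = as.integer(seed)),
            class = "mr_config")
}

# susceptibility phase prefactor (rad/s at the cylinder surface factor)
# for a deoxygenation level (1 - Y)
mr_prefactor <- function(mr, one_minus_y) {
  2 * pi * mr$gamma_rad_per_s_per_T * mr$b0_T *
    mr$dchi0_ppm_cgs * 1e-6 * mr$hct * one_minus_y
}

# unit-susceptibility phases for one (V, r) state; list of per-geometry
# phase vectors.  Walk and geometry seeds depend only on (seed, geometry
# index) -- not on V, Y or radius -- so paired states share random numbers
# and differences along any LuT axis are common-random-number comparisons.
mr_unit_phases <- function(vol_frac, radius_um, mr) {
  n_steps <- as.integer(round(mr$te_s / mr$dt_s))
  d_um2_per_s <- mr$d_water_m2_per_s * 1e12
  lapply(seq_len(mr$n_geom), function(gi) {
    sg <- as.integer((as.numeric(mr$seed) * 131071 + gi * 7919) %%
                       2147483647)
    sw <- as.integer((as.numeric(sg) * 48271 + 977) %% 2147483647)
    .mr_mc_phases_cpp(vol_frac, radius_um, mr$n_protons, n_steps, mr$dt_s,
                      d_um2_per_s, mr$n_cylinders, sg, sw, TRUE)$phi_unit
  })
}

# |mean exp(i c phi)| -> R2* (per s)
r2star_from_phases <- function(phases, c_scale, te_s) {
  vapply(phases, function(phi) {
    s <- Mod(mean(exp(1i * c_scale * phi)))
    -log(max(s, 1e-12)) / te_s
  }, numeric(1))
}

#' Extravascular gradient-echo attenuation change
#'
#' Monte Carlo estimate of the change in effective transverse relaxation
#' rate when the tissue moves from a baseline state `(v0, y0)` to a state
#' `(V, Y)`: randomly oriented vessel cylinders occupying volume fraction V
#' of a periodic voxel perturb the field according to the infinite-cylinder
#' dipole pattern with susceptibility offset proportional to `hct * (1 -
#' Y)`, extravascular protons random-walk through the perturbation, and the
#' echo signal is the magnitude of the mean phasor at TE.  Identical seeds
#' are used for state and baseline, so `dR2* = 0` exactly when the state
#' equals the baseline.
#'
#' @param V vessel volume fraction (0 < V < 0.2).
#' @param Y haemoglobin saturation in `[0, 1]`.
#' @param radius_um vessel radius (um).
#' @param mr an [mr_config()].
#' @param v0,y0 baseline state.
#' @param reflect reflect protons elastically at vessel walls (`FALSE`
#'   rejects the step instead; used for robustness checks).
#' @return `dR2*` in s^-1 (averaged over `n_geom` geometries), with
#'   attributes `se` (geometry scatter) and `warning_low_protons`.
#' @export
ev_delta_r2star <- function(V, Y, radius_um, mr, v0 = 0.06, y0 = 0.5,
                            reflect = TRUE) {
  stopifnot(inherits(mr, "mr_config"))
  if (V <= 0 || V >= 0.2) stop("V must lie in (0, 0.2)")
  if (Y < 0 || Y > 1) stop("Y must lie in [0, 1]")
  low_protons <- mr$n_protons < 100
  n_steps <- as.integer(round(mr$te_s / mr$dt_s))
  d_um2_per_s <- mr$d_water_m2_per_s * 1e12
  vals <- vapply(seq_len(mr$n_geom), function(gi) {
    sg <- as.integer((as.numeric(mr$seed) * 131071 + gi * 7919) %%
                       2147483647)
    sw <- as.integer((as.numeric(sg) * 48271 + 977) %% 2147483647)
    ph1 <- .mr_mc_phases_cpp(V, radius_um, mr$n_protons, n_steps, mr$dt_s,
                             d_um2_per_s, mr$n_cylinders, sg, sw,
                             reflect)$phi_unit
    ph0 <- .mr_mc_phases_cpp(v0, radius_um, mr$n_protons, n_steps, mr$dt_s,
                             d_um2_per_s, mr$n_cylinders, sg, sw,
                             reflect)$phi_unit
    r1 <- -log(max(Mod(mean(exp(1i * mr_prefactor(mr, 1 - Y) * ph1))),
                   1e-12)) / mr$te_s
    r0 <- -log(max(Mod(mean(exp(1i * mr_prefactor(mr, 1 - y0) * ph0))),
                   1e-12)) / mr$te_s
    r1 - r0
  }, numeric(1))
  out <- mean(vals)
  attr(out, "se") <- if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else NA_real_
  attr(out, "warning_low_protons") <- low_protons
  out
}

#' Tabulate extravascular dR2* over volume, saturation and radius
#'
#' Runs the dephasing Monte Carlo once per (volume fraction, radius) node
#' and evaluates every saturation node by rescaling the accumulated unit
#' phases (the walk geometry does not depend on Y, so the rescaling is
#' exact).  The stored table holds raw `R2*(V, Y, r)`; the accessor
#' [bold_delta_r2star()] subtracts the interpolated value at the baseline
#' state, so the anchor `dR2*(baseline) = 0` holds by construction.
#'
#' @param mr an [mr_config()].
#' @param v_grid,y_grid,r_grid strictly increasing grids; must cover the
#'   baseline state.
#' @param v0,y0 default baseline state stored with the table.
#' @return An `ois_bold_lut` object.
#' @export
build_bold_lut <- function(mr,
                           v_grid = seq(0.02, 0.12, by = 0.01),
                           y_grid = seq(0.1, 0.98, by = 0.04),
                           r_grid = c(3, 10, 20),
                           v0 = 0.06, y0 = 0.5) {
  stopifnot(inherits(mr, "mr_config"))
  for (g in list(v_grid, y_grid, r_grid))
    if (is.unsorted(g, strictly = TRUE)) stop("grids must be strictly increasing")
  if (v0 < v_grid[1] || v0 > v_grid[length(v_grid)] ||
      y0 < y_grid[1] || y0 > y_grid[length(y_grid)])
    stop("grids must cover the baseline state")
  nv <- length(v_grid); nyg <- length(y_grid); nr <- length(r_grid)
  r2 <- array(0, dim = c(nv, nyg, nr))
  pref <- mr_prefactor(mr, 1 - y_grid)
  for (ir in seq_len(nr)) {
    for (iv in seq_len(nv)) {
      phases <- mr_unit_phases(v_grid[iv], r_grid[ir], mr)
      for (iy in seq_len(nyg)) {
        r2[iv, iy, ir] <- mean(r2star_from_phases(phases, pref[iy], mr$te_s))
      }
    }
  }
  structure(list(r2star = r2, v_grid = v_grid, y_grid = y_grid,
                 r_grid = r_grid, v0 = v0, y0 = y0,
                 config_hash = object_hash(unclass(mr)),
                 n_protons = mr$n_protons, n_geom = mr$n_geom,
                 seed = mr$seed, te_s = mr$te_s),
            class = "ois_bold_lut")
}

# linear interpolation helper: index + fraction along a grid, clamped
grid_locate <- function(x, grid) {
  n <- length(grid)
  xc <- pmin(pmax(x, grid[1]), grid[n])
  clipped <- sum(x < grid[1] | x > grid[n])
  i <- findInterval(xc, grid, rightmost.closed = TRUE)
  i[i >= n] <- n - 1L
  f <- (xc - grid[i]) / (grid[i + 1L] - grid[i])
  list(i = i, f = f, clipped = clipped)
}

#' Interpolated dR2* relative to baseline
#'
#' Trilinear interpolation of the tabulated `R2*` minus the interpolated
#' value at the baseline state.  Values outside the grids are clamped to the
#' edges; the number of clamped points is returned in the `clipped`
#' attribute.
#'
#' @param blut a [build_bold_lut()] table.
#' @param V,Y numeric vectors (recycled against each other).
#' @param radius_um scalar radius.
#' @param v0,y0 baseline override; default the table's stored baseline.
#' @return Vector of `dR2*` values (s^-1).
#' @export
bold_delta_r2star <- function(blut, V, Y, radius_um,
                              v0 = blut$v0, y0 = blut$y0) {
  stopifnot(inherits(blut, "ois_bold_lut"))
  n <- max(length(V), length(Y))
  V <- rep_len(V, n); Y <- rep_len(Y, n)
  lv <- grid_locate(V, blut$v_grid)
  ly <- grid_locate(Y, blut$y_grid)
  lr <- grid_locate(radius_um, blut$r_grid)
  interp <- function(iv, fv, iy, fy) {
    acc <- 0
    for (dv in 0:1) for (dy in 0:1) for (dr in 0:1) {
      wv <- if (dv == 0) 1 - fv else fv
      wy <- if (dy == 0) 1 - fy else fy
      wr <- if (dr == 0) 1 - lr$f else lr$f
      acc <- acc + wv * wy * wr *
        blut$r2star[cbind(iv + dv, iy + dy, lr$i + dr)]
    }
    acc
  }
  val <- interp(lv$i, lv$f, ly$i, ly$f)
  l0v <- grid_locate(v0, blut$v_grid)
  l0y <- grid_locate(y0, blut$y_grid)
  base <- interp(l0v$i, l0v$f, l0y$i, l0y$f)
  out <- val - base
  attr(out, "clipped") <- lv$clipped + ly$clipped
  out
}

#' Save / load a BOLD lookup table as JSON
#' @param blut an `ois_bold_lut`.
#' @param path file path.
#' @export
save_bold_lut <- function(blut, path) {
  obj <- unclass(blut)
  obj$r2star <- list(dim = dim(blut$r2star), values = as.vector(blut$r2star))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bold_lut
#' @export
load_bold_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$r2star <- array(obj$r2star$values, dim = obj$r2star$dim)
  structure(obj, class = "ois_bold_lut")
}

#' Predict extravascular BOLD from a haemodynamic field
#'
#' Maps micromolar haemoglobin changes to fractional gradient-echo signal
#' changes.  Per pixel and frame the tissue state is
#' `V = v0 * (hbt0 + dHbT) / hbt0` and
#' `Y = (hbo2_0 + dHbO2) / (hbt0 + dHbT)` (clipped to `[0, 1]` with a QC
#' count), and the BOLD fraction is `exp(-dR2*(V, Y, r) * TE) - 1`,
#' evaluated at the low, mid and high radii of the vessel-radius envelope.
#' Baseline quantities come from the superficial (first) layer of the
#' supplied baseline state.
#'
#' @param field an `ois_field` (ground truth or PLSA-recovered).
#' @param baseline a [baseline_concentrations()] state.
#' @param blut a [build_bold_lut()] table.
#' @param mr an [mr_config()].
#' @param radii_um radii evaluated, default `c(low, mid, high)` with mid
#'   10 um.
#' @param y0 baseline saturation override (sweep support).
#' @return An `ois_bold_prediction`: arrays `central`, `lower`, `upper`
#'   (elementwise min/central/max over the radii), the radii, and QC
#'   counters.
#' @export
predict_bold <- function(field, baseline, blut, mr, radii_um = NULL,
                         y0 = NULL) {
  stopifnot(inherits(field, "ois_field"), inherits(baseline, "ois_baseline"),
            inherits(blut, "ois_bold_lut"), inherits(mr, "mr_config"))
  if (is.null(radii_um))
    radii_um <- c(mr$radius_um_range[1],
                  10, mr$radius_um_range[2])
  hbt0 <- baseline$hbt0[1]
  hbo2_0 <- baseline$hbo2_0[1]
  base_y0 <- if (is.null(y0)) baseline$y0[1] else y0
  v0 <- baseline$blood_volume[1]
  dims <- dim(field$d_hbt)
  hbt <- hbt0 + as.vector(field$d_hbt)
  hbt[hbt < 1e-6] <- 1e-6
  Y <- (hbo2_0 + as.vector(field$d_hbo2)) / hbt
  n_clip <- sum(Y < 0 | Y > 1)
  Y <- pmin(pmax(Y, 0), 1)
  V <- v0 * hbt / hbt0
  per_r <- lapply(radii_um, function(r) {
    dr2 <- bold_delta_r2star(blut, V, Y, r, v0 = v0, y0 = base_y0)
    array(exp(-as.vector(dr2) * mr$te_s) - 1, dim = dims)
  })
  lower <- Reduce(pmin, per_r)
  upper <- Reduce(pmax, per_r)
  central <- per_r[[ceiling(length(per_r) / 2)]]
  structure(list(central = central, lower = lower, upper = upper,
                 radii_um = radii_um,
                 radius_low = radii_um[1],
                 radius_high = radii_um[length(radii_um)],
                 time_s = field$time_s, rate_hz = field$rate_hz,
                 qc = list(n_saturation_clipped = n_clip)),
            class = "ois_bold_prediction")
}

#' Baseline-saturation sensitivity sweep
#'
#' Re-analyses the same four-wavelength stack at each candidate baseline
#' saturation: rebuild the baseline state, invert with the PLSA, feed the
#' recovered haemodynamics through the MR attenuation model at the
#' mid-range vessel radius, and record the peak absolute fractional BOLD
#' change of the region-mean time series.
#'
#' @param stack an `ois_stack`.
#' @param lut photon path-length table for `tissue`.
#' @param tissue analysis [tissue_model()].
#' @param optics an [optical_constants()].
#' @param mr an [mr_config()].
#' @param blut a [build_bold_lut()] whose saturation grid covers the sweep.
#' @param mask logical region mask (`y x x`), the region whose mean series
#'   is scored.
#' @param y0_grid candidate baseline saturations, each in (0, 1).
#' @param blood_hbt_uM whole-blood haemoglobin concentration.
#' @return A list with `table` (data.frame `y0`, `peak_abs_bold`),
#'   `argmax_y0`, and the per-Y0 region series.
#' @export
y0_sweep <- function(stack, lut, tissue, optics, mr, blut, mask,
                     y0_grid = seq(0.3, 0.9, by = 0.1),
                     blood_hbt_uM = 104 / 0.06) {
  if (!length(y0_grid)) stop("y0_grid must be non-empty")
  if (any(y0_grid <= 0 | y0_grid >= 1)) stop("y0 values must lie in (0, 1)")
  series <- list()
  peaks <- numeric(length(y0_grid))
  for (i in seq_along(y0_grid)) {
    b <- baseline_concentrations(tissue, optics, blood_hbt_uM,
                                 y0 = y0_grid[i])
    rec <- plsa_invert(stack, lut, b)
    pred <- predict_bold(rec, b, blut, mr, radii_um = 10, y0 = y0_grid[i])
    ts <- apply_mask_mean(pred$central, mask)
    series[[i]] <- ts
    peaks[i] <- max(abs(ts))
  }
  tab <- data.frame(y0 = y0_grid, peak_abs_bold = peaks)
  list(table = tab, argmax_y0 = y0_grid[which.max(peaks)], series = series)
}

# mean over a 2D mask of a [time, y, x] array
apply_mask_mean <- function(arr, mask) {
  stopifnot(length(dim(arr)) == 3L, is.logical(mask))
  m <- matrix(arr, dim(arr)[1], dim(arr)[2] * dim(arr)[3])
  rowMeans(m[, as.vector(mask), drop = FALSE])
}
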