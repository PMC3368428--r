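#' Monte Carlo photon transport through layered tissue
#'
#' Launches photons normally onto the tissue surface and tracks them through
#' scattering, absorption (by statistical weight deposition), layer
#' crossings and remittance.  Step lengths are sampled against the total
#' attenuation of the current layer and directions against the
#' Henyey-Greenstein phase function.  The refractive index is matched at the
#' surface (the imaging well is fluid-filled), so photons reaching z = 0
#' upward leave the tissue and are scored as remitted together with the path
#' they traversed in each layer.  Photon weight is conserved exactly:
#' Russian-roulette kills are credited to the absorbed bucket and survivor
#' boosts debited from it.
#'
#' @param tissue a [tissue_model()]; supplies layer geometry and, unless
#'   overridden, scattering properties.
#' @param mua_per_mm per-layer absorption coefficients (mm^-1), recycled to
#'   the number of layers.
#' @param mus_per_mm,g optional per-layer scattering overrides; default the
#'   tissue model's values.
#' @param n_photons number of photons to launch (>= 1).
#' @param seed integer seed for the internal generator.
#' @param w_cutoff,p_survive Russian-roulette weight cutoff and survival
#'   probability.
#' @return A list with `mean_path_mm` (weighted mean partial path per layer
#'   over remitted photons), `mean_total_path_mm`, `se_total_path_mm`,
#'   `remitted_fraction`, `absorbed_fraction`, `transmitted_fraction`,
#'   `n_remitted`, `path_depth_ok_fraction` and the logical `empty` flag
#'   (set when no photon was remitted; path entries are then zero, never
#'   NaN).
#' @export
simulate_photons <- function(tissue, mua_per_mm, mus_per_mm = NULL, g = NULL,
                             n_photons = 10000, seed = 1,
                             w_cutoff = 1e-4, p_survive = 0.1) {
  stopifnot(inherits(tissue, "tissue_model"))
  nl <- n_layers(tissue)
  mua <- rep_len(mua_per_mm, nl)
  mus <- if (is.null(mus_per_mm)) layer_field(tissue, "mus_per_mm") else
    rep_len(mus_per_mm, nl)
  gg <- if (is.null(g)) layer_field(tissue, "g") else rep_len(g, nl)
  if (any(mua < 0) || any(mus < 0)) stop("optical coefficients must be >= 0")
  if (n_photons < 1) stop("n_photons must be >= 1")
  res <- .photon_mc_cpp(layer_field(tissue, "z_top_mm"),
                        layer_field(tissue, "z_bottom_mm"),
                        mua, mus, gg,
                        as.integer(n_photons), as.integer(seed),
                        w_cutoff, p_survive)
  res$weight_balance <- res$remitted_fraction + res$absorbed_fraction +
    res$transmitted_fraction
  res
}

#' Build a path-length lookup table
#'
#' Tabulates the mean per-layer partial path length of remitted photons over
#' the four filter bands and a grid of absorption coefficients.  Each grid
#' node applies the same absorption coefficient to every layer; the
#' spectroscopic inversion then reads each layer's partial path at that
#' layer's own current absorption.  Scattering is held at the tissue model's
#' per-layer values for every band.
#'
#' @param tissue a [tissue_model()].
#' @param optics an [optical_constants()] object (supplies the bands).
#' @param mua_grid strictly increasing absorption grid (mm^-1); must span
#'   the baseline absorption of every layer and band with margin for the
#'   expected haemodynamic excursions.
#' @param n_photons photons per (band, grid node) simulation.
#' @param seed integer seed; node simulations use deterministic offsets.
#' @return An object of class `ois_plut` holding the path-length array
#'   `[band, mua, layer]`, the remitted fraction per node, the grids, and
#'   metadata (`n_photons`, `seed`, tissue model hash).
#' @export
build_lut <- function(tissue, optics,
                      mua_grid = c(0.03, 0.06, 0.12, 0.2, 0.35,
                                   0.6, 1, 1.6, 2.5, 4),
                      n_photons = 20000, seed = 1) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(optics, "ois_optics"))
  if (is.unsorted(mua_grid, strictly = TRUE))
    stop("mua_grid must be strictly increasing")
  nb <- length(optics$bands_nm)
  nl <- n_layers(tissue)
  ng <- length(mua_grid)
  pl <- array(0, dim = c(nb, ng, nl))
  remit <- matrix(0, nb, ng)
  for (b in seq_len(nb)) {
    for (i in seq_len(ng)) {
      r <- simulate_photons(tissue, mua_grid[i], n_photons = n_photons,
                            seed = seed + 1000L * b + i)
      pl[b, i, ] <- r$mean_path_mm
      remit[b, i] <- r$remitted_fraction
    }
  }
  structure(list(pathlength_mm = pl, remitted = remit,
                 mua_grid = mua_grid, bands_nm = optics$bands_nm,
                 n_layers = nl, n_photons = n_photons, seed = seed,
                 tissue_hash = object_hash(unclass(tissue))),
            class = "ois_plut")
}

#' Interpolated path-length lookup
#'
#' Piecewise-linear interpolation of the stored per-layer path lengths along
#' the absorption axis; exact at grid nodes, no extrapolation.
#'
#' @param lut an [build_lut()] table.
#' @param band band index (1-based).
#' @param mua absorption coefficient(s), mm^-1, within the grid range.
#' @return Matrix `length(mua) x n_layers` of partial path lengths (mm).
#' @export
lookup_pathlength <- function(lut, band, mua) {
  stopifnot(inherits(lut, "ois_plut"))
  if (band < 1 || band > length(lut$bands_nm)) stop("band index out of range")
  g <- lut$mua_grid
  bad <- which(mua < g[1] | mua > g[length(g)])
  if (length(bad))
    stop(sprintf(
      "absorption coefficient %.4g /mm outside LuT range [%.4g, %.4g] at band %g nm (element %d)",
      mua[bad[1]], g[1], g[length(g)], lut$bands_nm[band], bad[1]))
  if (length(g) == 1L)   # degenerate grid: exact at its single node
    return(matrix(lut$pathlength_mm[band, 1, ], length(mua), lut$n_layers,
                  byrow = TRUE))
  idx <- findInterval(mua, g, rightmost.closed = TRUE)
  idx[idx >= length(g)] <- length(g) - 1L
  frac <- (mua - g[idx]) / (g[idx + 1L] - g[idx])
  lo <- lut$pathlength_mm[band, idx, , drop = FALSE]
  hi <- lut$pathlength_mm[band, idx + 1L, , drop = FALSE]
  out <- matrix(lo, length(mua), lut$n_layers) * (1 - frac) +
    matrix(hi, length(mua), lut$n_layers) * frac
  out
}

#' Save / load a path-length lookup table as JSON
#'
#' @param lut an `ois_plut` object.
#' @param path file path.
#' @return `load_plut` returns the restored `ois_plut`.
#' @export
save_plut <- function(lut, path) {
  stopifnot(inherits(lut, "ois_plut"))
  obj <- unclass(lut)
  obj$pathlength_mm <- list(dim = dim(lut$pathlength_mm),
                            values = as.vector(lut$pathlength_mm))
  obj$remitted <- list(dim = dim(lut$remitted),
                       values = as.vector(lut$remitted))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_plut
#' @export
load_plut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pathlength_mm <- array(obj$pathlength_mm$values,
                             dim = obj$pathlength_mm$dim)
  obj$remitted <- array(obj$remitted$values, dim = obj$remitted$dim)
  obj$n_photons <- as.numeric(obj$n_photons)
  obj$seed <- as.numeric(obj$seed)
  structure(obj, class = "ois_plut")
}
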