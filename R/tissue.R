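#' Tissue layer for layered photon transport
#'
#' One optical layer of the cortical tissue model.  Depths are measured from
#' the surface (z = 0).
#'
#' @param z_top_mm,z_bottom_mm layer extent in mm, `z_bottom_mm > z_top_mm`.
#' @param blood_volume_fraction dimensionless baseline blood volume fraction.
#' @param y0 baseline haemoglobin oxygen saturation fraction in `[0, 1]`.
#' @param mus_per_mm scattering coefficient (mm^-1), `> 0`.
#' @param g scattering anisotropy, in `(-1, 1)`.
#' @param mua_background_per_mm non-haem background absorption (mm^-1).
#' @return A `tissue_layer` list.
#' @export
tissue_layer <- function(z_top_mm, z_bottom_mm, blood_volume_fraction,
                         y0 = 0.5, mus_per_mm = 20, g = 0.9,
                         mua_background_per_mm = 0.02) {
  if (z_bottom_mm <= z_top_mm) stop("z_bottom_mm must exceed z_top_mm")
  if (y0 < 0 || y0 > 1) stop("y0 must lie in [0, 1]")
  if (mus_per_mm <= 0) stop("mus_per_mm must be positive")
  if (abs(g) >= 1) stop("g must lie in (-1, 1)")
  if (blood_volume_fraction < 0 || blood_volume_fraction > 0.5)
    stop("blood_volume_fraction out of range")
  structure(list(z_top_mm = z_top_mm, z_bottom_mm = z_bottom_mm,
                 blood_volume_fraction = blood_volume_fraction, y0 = y0,
                 mus_per_mm = mus_per_mm, g = g,
                 mua_background_per_mm = mua_background_per_mm),
            class = "tissue_layer")
}

#' Layered cortical tissue model
#'
#' Assembles contiguous [tissue_layer()]s into a tissue model for photon
#' transport and spectroscopic analysis.  Two stock models are provided:
#' [homogeneous_tissue()] (a single slab, 6% blood volume, the model
#' conventionally used in imaging spectroscopy) and [heterogeneous_tissue()]
#' (a five-layer model with 6% blood volume in the superficial 0-1 mm and 4%
#' in deeper layers, giving greater weight to deep cortical haemodynamics).
#'
#' @param layers list of [tissue_layer()] objects, contiguous from z = 0.
#' @param kind `"homogeneous"` or `"heterogeneous"`.
#' @return A `tissue_model` object.
#' @export
tissue_model <- function(layers, kind = c("heterogeneous", "homogeneous")) {
  kind <- match.arg(kind)
  if (!length(layers)) stop("at least one layer required")
  if (abs(layers[[1]]$z_top_mm) > 1e-12) stop("layers must start at z = 0")
  if (length(layers) > 1)
    for (i in 2:length(layers))
      if (abs(layers[[i]]$z_top_mm - layers[[i - 1]]$z_bottom_mm) > 1e-9)
        stop("layers must be contiguous")
  if (kind == "homogeneous" && length(layers) != 1L)
    stop("homogeneous model must have exactly one layer")
  structure(list(layers = layers, kind = kind), class = "tissue_model")
}

#' @rdname tissue_model
#' @param y0 baseline oxygen saturation applied to every layer.
#' @param depth_mm total modelled depth (mm).
#' @export
homogeneous_tissue <- function(y0 = 0.5, depth_mm = 10) {
  tissue_model(list(tissue_layer(0, depth_mm, 0.06, y0 = y0)),
               kind = "homogeneous")
}

#' @rdname tissue_model
#' @param boundaries_mm layer boundary depths; defaults
#'   `c(0, 0.3, 0.6, 1, 2, 10)` giving five layers.
#' @param blood_volume per-layer baseline blood volume fractions; default 6%
#'   above 1 mm and 4% below.
#' @export
heterogeneous_tissue <- function(boundaries_mm = c(0, 0.3, 0.6, 1, 2, 10),
                                 blood_volume = NULL, y0 = 0.5) {
  nb <- length(boundaries_mm) - 1L
  if (nb < 2) stop("heterogeneous model needs at least two layers")
  if (is.null(blood_volume))
    blood_volume <- ifelse(boundaries_mm[-1] <= 1 + 1e-9, 0.06, 0.04)
  if (length(blood_volume) != nb) stop("one blood volume per layer required")
  layers <- lapply(seq_len(nb), function(i)
    tissue_layer(boundaries_mm[i], boundaries_mm[i + 1], blood_volume[i],
                 y0 = y0))
  tissue_model(layers, kind = "heterogeneous")
}

n_layers <- function(tissue) length(tissue$layers)

layer_field <- function(tissue, what) {
  vapply(tissue$layers, `[[`, numeric(1), what)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("%s tissue model, %d layer(s)\n", x$kind, n_layers(x)))
  print(data.frame(z_top_mm = layer_field(x, "z_top_mm"),
                   z_bottom_mm = layer_field(x, "z_bottom_mm"),
                   blood_volume = layer_field(x, "blood_volume_fraction"),
                   y0 = layer_field(x, "y0"),
                   mus_per_mm = layer_field(x, "mus_per_mm"),
                   g = layer_field(x, "g")))
  invisible(x)
}

# Per-layer weights describing how a depth profile distributes a
# concentration change across the layers of a tissue model.  `profile` is
# "superficial" (0-1 mm), "deep" (1-2 mm), "uniform", or an explicit numeric
# weight vector (one entry per layer); weights are blood-volume weighted
# within the depth range and normalised to sum to 1.
depth_profile_weights <- function(tissue, profile) {
  nl <- n_layers(tissue)
  if (is.numeric(profile)) {
    if (length(profile) != nl) stop("need one depth weight per layer")
    if (any(profile < 0) || sum(profile) <= 0) stop("invalid depth weights")
    return(profile / sum(profile))
  }
  zt <- layer_field(tissue, "z_top_mm")
  zb <- layer_field(tissue, "z_bottom_mm")
  bv <- layer_field(tissue, "blood_volume_fraction")
  rng <- switch(match.arg(profile, c("superficial", "deep", "uniform")),
                superficial = c(0, 1), deep = c(1, 2),
                uniform = c(0, max(zb)))
  overlap <- pmax(0, pmin(zb, rng[2]) - pmax(zt, rng[1]))
  w <- overlap * bv
  if (sum(w) <= 0) w <- overlap      # e.g. single slab fully covering range
  if (sum(w) <= 0) w <- rep(1, nl)   # degenerate: fall back to uniform
  w / sum(w)
}
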