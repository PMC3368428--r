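# Shared fixtures, built lazily and cached for the whole test run.  Monte
# Carlo sizes are reduced relative to the package defaults; every consumer
# states the statistical tolerance it needs.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_optics <- function() fx("optics", optical_constants)

fx_lut_hom <- function() fx("lut_hom", function()
  build_lut(homogeneous_tissue(), fx_optics(), n_photons = 10000, seed = 5))

fx_lut_het <- function() fx("lut_het", function()
  build_lut(heterogeneous_tissue(), fx_optics(), n_photons = 8000,
            seed = 6))

fx_mr <- function() fx("mr", function()
  mr_config(n_protons = 4000, n_geom = 3, seed = 3))

fx_blut <- function() fx("blut", function() build_bold_lut(fx_mr()))

# positive-region trial-window stack (noise free) and its field
fx_positive_world <- function() fx("positive_world", function() {
  p <- make_paradigm()
  tis <- homogeneous_tissue()
  f <- trial_window_field(p, list(positive_region()), grid_px = c(44, 44))
  stack <- render_wavelength_stack(f, tis, fx_lut_hom(), fx_optics())
  list(paradigm = p, tissue = tis, field = f, stack = stack,
       mask = f$region_masks[[1]],
       baseline = baseline_concentrations(tis, fx_optics()))
})

# one reduced-MC end-to-end run on the default synthetic world, shared by
# the pipeline unit tests and the acceptance suite
fx_pipeline <- function() fx("pipeline", function() {
  cfg <- run_config(mr = mr_config(n_protons = 3000, n_geom = 2, seed = 3),
                    n_photons_lut = 6000, seed = 7)
  luts <- list(
    true = build_lut(heterogeneous_tissue(), cfg$optics, cfg$mua_grid,
                     n_photons = cfg$n_photons_lut, seed = cfg$seed),
    hom = build_lut(homogeneous_tissue(), cfg$optics, cfg$mua_grid,
                    n_photons = cfg$n_photons_lut, seed = cfg$seed + 1L))
  luts$het <- luts$true
  luts$bold <- build_bold_lut(cfg$mr, cfg$v_grid, cfg$y_grid, cfg$r_grid)
  list(config = cfg, report = run_pipeline(cfg, luts = luts))
})
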