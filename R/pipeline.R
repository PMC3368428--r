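#' Pearson correlation and regression gradient of prediction on measurement
#'
#' The prediction-evaluation statistic: Pearson correlation between the two
#' series and the ordinary least-squares slope of `predicted` regressed on
#' `measured` (free intercept).  A gradient of 1 means the prediction
#' reproduces the measured response magnitude; below 1 it under-estimates
#' it.
#'
#' @param predicted,measured numeric series of equal length (>= 3).
#' @return List with `correlation` and `gradient`.
#' @export
compare_timeseries <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("series lengths differ")
  if (length(predicted) < 3) stop("need at least 3 points")
  if (sd(predicted) == 0 || sd(measured) == 0)
    stop("zero variance series")
  list(correlation = cor(predicted, measured),
       gradient = unname(coef(lm(predicted ~ measured))[2]))
}

#' Pipeline run configuration
#'
#' Gathers every knob of the end-to-end run.  Scalar overrides are applied
#' on top of defaults that emulate the study conditions; Monte Carlo sizes
#' may be reduced for quick runs without touching the physics.
#'
#' @param paradigm an [make_paradigm()] object.
#' @param regions region list for the generator.
#' @param grid_px optical grid (pixels).
#' @param pixel_um optical pixel size (um).
#' @param true_tissue tissue model used to render the synthetic stack (the
#'   "true" cortex; heterogeneous by default since the generated surround
#'   response is deep).
#' @param optics an [optical_constants()] object.
#' @param mr an [mr_config()].
#' @param mua_grid,n_photons_lut photon LuT settings.
#' @param v_grid,y_grid,r_grid BOLD LuT grids.
#' @param stack_noise_sd attenuation noise of the trial-collapsed stack.
#' @param fmri_noise_sd fMRI noise fraction per frame.
#' @param z_pos,z_neg,min_cluster,connectivity GLM mapping rule.
#' @param smooth_sigma_um Gaussian smoothing of the fMRI parameter map.
#' @param scale_grid,angle_grid affine search grids.
#' @param seed master integer seed.
#' @param out_dir output directory (created); `NULL` for an in-memory run.
#' @return A validated `run_config`.
#' @export
run_config <- function(paradigm = make_paradigm(),
                       regions = list(positive_region(), negative_region()),
                       grid_px = c(64, 64), pixel_um = 80,
                       true_tissue = heterogeneous_tissue(),
                       optics = optical_constants(),
                       mr = mr_config(),
                       mua_grid = c(0.03, 0.06, 0.12, 0.2, 0.35,
                                    0.6, 1, 1.6, 2.5, 4),
                       n_photons_lut = 20000,
                       v_grid = seq(0.02, 0.12, by = 0.01),
                       y_grid = seq(0.1, 0.98, by = 0.04),
                       r_grid = c(3, 10, 20),
                       stack_noise_sd = 2e-4, fmri_noise_sd = 0.005,
                       z_pos = 4, z_neg = -2, min_cluster = 6,
                       connectivity = 4,
                       smooth_sigma_um = 489,
                       scale_grid = seq(0.10, 0.25, by = 0.01),
                       angle_grid = seq(-15, 15, by = 1),
                       seed = 1, out_dir = NULL) {
  stopifnot(inherits(paradigm, "ois_paradigm"),
            inherits(true_tissue, "tissue_model"),
            inherits(optics, "ois_optics"), inherits(mr, "mr_config"))
  if (!(z_pos > 0)) stop("z_pos must be positive")
  if (!(z_neg < 0)) stop("z_neg must be negative")
  if (min_cluster < 1) stop("min_cluster must be >= 1")
  if (stack_noise_sd < 0 || fmri_noise_sd < 0) stop("noise must be >= 0")
  cfg <- list(paradigm = paradigm, regions = regions, grid_px = grid_px,
              pixel_um = pixel_um, true_tissue = true_tissue,
              optics = optics, mr = mr, mua_grid = mua_grid,
              n_photons_lut = n_photons_lut, v_grid = v_grid,
              y_grid = y_grid, r_grid = r_grid,
              stack_noise_sd = stack_noise_sd,
              fmri_noise_sd = fmri_noise_sd, z_pos = z_pos, z_neg = z_neg,
              min_cluster = min_cluster, connectivity = connectivity,
              smooth_sigma_um = smooth_sigma_um, scale_grid = scale_grid,
              angle_grid = angle_grid, seed = as.integer(seed),
              out_dir = out_dir)
  cfg$hash <- object_hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

#' Ground-truth field over one trial window
#'
#' Generates the paradigm-locked field and crops a single trial window
#' (onset to onset + ISI).  With noise-free generation every trial is
#' identical, so this window equals the across-trial average the
#' spectroscopic analysis operates on.
#'
#' @param paradigm,regions,grid_px,pixel_um,rate_hz see
#'   [generate_haemodynamics()].
#' @return An `ois_field` of `round(isi_s * rate_hz)` frames starting at
#'   the stimulus onset.
#' @export
trial_window_field <- function(paradigm, regions,
                               grid_px = c(64, 64), pixel_um = 80,
                               rate_hz = paradigm$ois_rate_hz) {
  f <- generate_haemodynamics(paradigm, regions, grid_px = grid_px,
                              pixel_um = pixel_um, rate_hz = rate_hz,
                              duration_s = paradigm$baseline_s +
                                paradigm$isi_s)
  i0 <- round(paradigm$baseline_s * rate_hz) + 1L
  i1 <- i0 + round(paradigm$isi_s * rate_hz) - 1L
  f$d_hbo2 <- f$d_hbo2[i0:i1, , , drop = FALSE]
  f$d_hbr <- f$d_hbr[i0:i1, , , drop = FALSE]
  f$d_hbt <- f$d_hbt[i0:i1, , , drop = FALSE]
  f$time_s <- (seq_len(i1 - i0 + 1L) - 1) / rate_hz
  f
}

# cubic interpolation of a series onto a finer time base
interp_series <- function(y, rate_in_hz, rate_out_hz) {
  t_in <- (seq_along(y) - 1) / rate_in_hz
  n_out <- floor(t_in[length(t_in)] * rate_out_hz) + 1L
  t_out <- (seq_len(n_out) - 1) / rate_out_hz
  stats::spline(t_in, y, xout = t_out, method = "natural")$y
}

#' Run the full synthetic pipeline
#'
#' Executes the complete chain: generate ground-truth haemodynamics; build
#' photon path-length LuTs for the true, homogeneous-analysis and
#' heterogeneous-analysis tissue models; render the trial-collapsed
#' four-wavelength stack; generate the synthetic fMRI measurement; invert
#' the stack with both analysis models (PLSA); predict BOLD from each
#' recovery and from the ground truth; map both modalities with the
#' two-pass GLM; and compare predictions to measurements in time
#' (correlation + regression gradient) and space (affine template
#' correlation).  All stages are seeded from the config, so identical
#' configs give identical outputs.
#'
#' @param config a [run_config()].
#' @param luts optional list of precomputed lookup tables (`true`, `hom`,
#'   `het` photon LuTs and `bold`), as returned in `$objects$luts` of a
#'   previous run; when supplied the LuT-building stage is skipped.
#' @return A `ComparisonReport`-style list (regions x tissue models:
#'   correlation, gradient, envelope coverage; spatial match; QC), plus the
#'   intermediate objects in `$objects`.  When `config$out_dir` is set the
#'   report, manifest, maps and series are also written there; the report
#'   JSON is a pure function of the config, so identical configs give
#'   byte-identical reports (timings live in the manifest).
#' @export
run_pipeline <- function(config, luts = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  stage <- "setup"
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fail_marker <- function(e) {
    if (!is.null(out_dir))
      writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    p <- config$paradigm
    optics <- config$optics
    mr <- config$mr
    timings <- list()
    tic <- function() Sys.time()
    toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

    stage <- "luts"
    t0 <- tic()
    tis_true <- config$true_tissue
    tis_hom <- homogeneous_tissue()
    tis_het <- heterogeneous_tissue()
    if (is.null(luts)) {
      lut_true <- build_lut(tis_true, optics, config$mua_grid,
                            n_photons = config$n_photons_lut,
                            seed = config$seed)
      lut_hom <- if (identical(unclass(tis_true), unclass(tis_hom)))
        lut_true
      else build_lut(tis_hom, optics, config$mua_grid,
                     n_photons = config$n_photons_lut,
                     seed = config$seed + 1L)
      lut_het <- if (identical(unclass(tis_true), unclass(tis_het)))
        lut_true
      else build_lut(tis_het, optics, config$mua_grid,
                     n_photons = config$n_photons_lut,
                     seed = config$seed + 2L)
      blut <- build_bold_lut(mr, config$v_grid, config$y_grid,
                             config$r_grid)
    } else {
      lut_true <- luts$true; lut_hom <- luts$hom
      lut_het <- luts$het; blut <- luts$bold
    }
    timings$luts <- toc(t0)

    stage <- "generate"
    t0 <- tic()
    field_w <- trial_window_field(p, config$regions, config$grid_px,
                                  config$pixel_um)
    base_true <- baseline_concentrations(tis_true, optics)
    # trial-collapsed stack: noise scaled as an n-trial average
    stack <- render_wavelength_stack(
      field_w, tis_true, lut_true, optics,
      noise_sd = config$stack_noise_sd / sqrt(p$n_trials),
      seed = config$seed + 10L)
    field_fmri <- generate_haemodynamics(p, config$regions,
                                         grid_px = config$grid_px,
                                         pixel_um = config$pixel_um,
                                         rate_hz = 1 / p$fmri_tr_s)
    fmri <- generate_fmri(field_fmri, base_true, mr, blut,
                          noise_sd = config$fmri_noise_sd,
                          seed = config$seed + 20L, paradigm = p)
    timings$generate <- toc(t0)

    stage <- "invert"
    t0 <- tic()
    base_hom <- baseline_concentrations(tis_hom, optics)
    base_het <- baseline_concentrations(tis_het, optics)
    rec_hom <- plsa_invert(stack, lut_hom, base_hom)
    rec_het <- plsa_invert(stack, lut_het, base_het)
    timings$invert <- toc(t0)

    stage <- "predict"
    t0 <- tic()
    pred_hom <- predict_bold(rec_hom, base_hom, blut, mr)
    pred_het <- predict_bold(rec_het, base_het, blut, mr)
    pred_true <- predict_bold(field_w, base_true, blut, mr)
    timings$predict <- toc(t0)

    stage <- "glm_fmri"
    t0 <- tic()
    frac <- fmri_fractional(fmri, baseline_s = p$baseline_s)
    fr_fmri <- 1 / p$fmri_tr_s
    X1 <- build_design(p, fr_fmri)
    g1 <- fit_glm(frac, X1)
    masks1 <- threshold_clusters(g1$z, config$z_pos, config$z_neg,
                                 config$min_cluster, config$connectivity)
    if (!any(masks1$positive) || !any(masks1$negative))
      stop("preliminary fMRI mapping found no positive/negative cluster")
    # two-pass refinement from the positive-region mean
    ts_pos1 <- region_timeseries(frac, masks1$positive)
    X2 <- refine_design(X1, ts_pos1)
    g2 <- fit_glm(frac, X2)
    masks_fmri <- threshold_clusters(g2$z, config$z_pos, config$z_neg,
                                     config$min_cluster,
                                     config$connectivity)
    if (!any(masks_fmri$positive) || !any(masks_fmri$negative))
      masks_fmri <- masks1
    timings$glm_fmri <- toc(t0)

    stage <- "glm_prediction"
    t0 <- tic()
    rate_ois <- p$ois_rate_hz
    Xw <- build_design(p, rate_ois, duration_s = p$isi_s,
                       onset_shift_s = -p$baseline_s)
    gp1 <- fit_glm(pred_het$central, Xw)
    masks_p1 <- threshold_clusters(gp1$z, config$z_pos, config$z_neg,
                                   config$min_cluster, config$connectivity)
    if (!any(masks_p1$positive) || !any(masks_p1$negative))
      stop("prediction mapping found no positive/negative cluster")
    ts_posp <- region_timeseries(pred_het$central, masks_p1$positive)
    Xw2 <- refine_design(Xw, ts_posp)
    gp2 <- fit_glm(pred_het$central, Xw2)
    masks_pred <- threshold_clusters(gp2$z, config$z_pos, config$z_neg,
                                     config$min_cluster,
                                     config$connectivity)
    if (!any(masks_pred$positive) || !any(masks_pred$negative))
      masks_pred <- masks_p1
    timings$glm_prediction <- toc(t0)

    stage <- "compare_series"
    t0 <- tic()
    meas_fold <- list(
      positive = interp_series(
        region_timeseries(frac, masks_fmri$positive, fold = TRUE,
                          paradigm = p, rate_hz = fr_fmri),
        fr_fmri, rate_ois),
      negative = interp_series(
        region_timeseries(frac, masks_fmri$negative, fold = TRUE,
                          paradigm = p, rate_hz = fr_fmri),
        fr_fmri, rate_ois))
    series_of <- function(pred, mask) region_timeseries(pred$central, mask)
    report_regions <- list()
    for (rg in c("positive", "negative")) {
      mask_p <- masks_pred[[rg]]
      true_ts <- series_of(pred_true, mask_p)
      n_meas <- length(meas_fold[[rg]])
      entry <- list()
      for (model in c("heterogeneous", "homogeneous")) {
        pred <- if (model == "heterogeneous") pred_het else pred_hom
        ts <- series_of(pred, mask_p)
        cmp_meas <- compare_timeseries(ts[seq_len(n_meas)],
                                       meas_fold[[rg]])
        cmp_true <- compare_timeseries(ts, true_ts)
        lo <- region_timeseries(pred$lower, mask_p)
        hi <- region_timeseries(pred$upper, mask_p)
        cover <- mean(meas_fold[[rg]] >= lo[seq_len(n_meas)] &
                        meas_fold[[rg]] <= hi[seq_len(n_meas)])
        entry[[model]] <- list(
          correlation_vs_measured = cmp_meas$correlation,
          gradient_vs_measured = cmp_meas$gradient,
          correlation_vs_truth = cmp_true$correlation,
          gradient_vs_truth = cmp_true$gradient,
          envelope_coverage = cover,
          peak_abs_bold = max(abs(ts)))
      }
      entry$measured_peak_abs <- max(abs(meas_fold[[rg]]))
      report_regions[[rg]] <- entry
    }
    timings$compare_series <- toc(t0)

    stage <- "compare_spatial"
    t0 <- tic()
    vox_um <- fmri$fov_mm * 1000 / fmri$matrix_px
    map_meas <- smooth_map(g2$beta_maps$response, config$smooth_sigma_um,
                           vox_um)
    map_pred <- gp2$beta_maps$response
    match <- match_template(map_pred, map_meas,
                            scale_grid = config$scale_grid,
                            angle_grid = config$angle_grid)
    timings$compare_spatial <- toc(t0)

    stage <- "report"
    report <- list(
      regions = report_regions,
      spatial_match = list(scale = match$scale,
                           angle_deg = match$angle_deg,
                           tx_px = match$tx_px, ty_px = match$ty_px,
                           correlation = match$correlation),
      qc = list(
        plsa_nonconverged_hom = sum(!rec_hom$converged),
        plsa_nonconverged_het = sum(!rec_het$converged),
        saturation_clipped = pred_hom$qc$n_saturation_clipped +
          pred_het$qc$n_saturation_clipped,
        fmri_clusters_pos_vox = sum(masks_fmri$positive),
        fmri_clusters_neg_vox = sum(masks_fmri$negative)),
      config_hash = config$hash,
      seed = config$seed)

    if (!is.null(out_dir)) {
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           digits = NA, auto_unbox = TRUE, pretty = TRUE)
      manifest <- list(config_hash = config$hash, seed = config$seed,
                       package_version =
                         as.character(utils::packageVersion("oisbold")),
                       timings_s = lapply(timings, function(x)
                         round(x, 3)))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           digits = NA, auto_unbox = TRUE, pretty = TRUE)
      write_map_nifti(g2$z, file.path(out_dir, "fmri_zmap.nii.gz"),
                      pixel_mm = vox_um / 1000)
      write_map_nifti(gp2$z, file.path(out_dir, "prediction_zmap.nii.gz"),
                      pixel_mm = config$pixel_um / 1000)
      write_region_csv(rec_het, masks_pred$positive,
                       file.path(out_dir, "het_positive_series.csv"))
      write_region_csv(rec_het, masks_pred$negative,
                       file.path(out_dir, "het_negative_series.csv"))
    }
    report$objects <- list(
      field_window = field_w, stack = stack, fmri = fmri,
      rec_hom = rec_hom, rec_het = rec_het,
      pred_hom = pred_hom, pred_het = pred_het, pred_true = pred_true,
      masks_fmri = masks_fmri, masks_pred = masks_pred,
      glm_fmri = g2, glm_pred = gp2, measured_folded = meas_fold,
      luts = list(true = lut_true, hom = lut_hom, het = lut_het,
                  bold = blut))
    report$elapsed_s <- as.numeric(difftime(Sys.time(), t_start,
                                            units = "secs"))
    report
  }, error = fail_marker)
}
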