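#!/usr/bin/env Rscript
# GLM activation mapping of the synthetic fMRI (two-pass design refinement,
# z > 4 / z < -2 cluster thresholds) and of the predicted-BOLD stack, then
# affine template correlation between the prediction parameter map and the
# smoothed fMRI map.
#
# Needs: 01_simulate.R, 04_predict_bold.R
# Outputs: results/glm/{fmri,prediction}_zmap.nii.gz, match.json

suppressPackageStartupMessages(library(oisbold))
out <- "results/glm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

paradigm <- read_paradigm_yaml("results/sim/paradigm.yaml")
fmri <- readRDS("results/sim/fmri.rds")
pred_het <- readRDS("results/predict/pred_het.rds")

frac <- fmri_fractional(fmri, baseline_s = paradigm$baseline_s)
X1 <- build_design(paradigm, 1 / paradigm$fmri_tr_s)
g1 <- fit_glm(frac, X1)
masks1 <- threshold_clusters(g1$z)
X2 <- refine_design(X1, region_timeseries(frac, masks1$positive))
g2 <- fit_glm(frac, X2)
masks <- threshold_clusters(g2$z)
message(sprintf("fMRI clusters: %d positive voxels (z > 4), %d negative (z < -2)",
                sum(masks$positive), sum(masks$negative)))

Xw <- build_design(paradigm, paradigm$ois_rate_hz,
                   duration_s = paradigm$isi_s,
                   onset_shift_s = -paradigm$baseline_s)
gp <- fit_glm(pred_het$central, Xw)

vox_um <- fmri$fov_mm * 1000 / fmri$matrix_px
map_meas <- smooth_map(g2$beta_maps$response, 489, vox_um)
match <- match_template(gp$beta_maps$response, map_meas)
print(match)
message(sprintf("(expected optics-to-fMRI scale: 80/%0.0f = %.3f)",
                vox_um, 80 / vox_um))

write_map_nifti(g2$z, file.path(out, "fmri_zmap.nii.gz"),
                pixel_mm = vox_um / 1000)
write_map_nifti(gp$z, file.path(out, "prediction_zmap.nii.gz"),
                pixel_mm = 0.08)
jsonlite::write_json(
  list(scale = match$scale, angle_deg = match$angle_deg,
       tx_px = match$tx_px, ty_px = match$ty_px,
       correlation = match$correlation),
  file.path(out, "match.json"), auto_unbox = TRUE, digits = NA)
message("done: ", out)
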