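#!/usr/bin/env Rscript
# Generate the synthetic study: trial-locked positive (whisker-barrel-like)
# and negative (surround) haemodynamic responses on an 80 um optical grid,
# the trial-collapsed four-wavelength attenuation stack, and the concurrent
# 64 x 64 EPI-like BOLD series (TR 1 s, FOV 30 mm).
#
# Outputs (results/):
#   sim/field_window.rds, sim/stack.rds, sim/fmri.rds   (intermediates)
#   sim/region_series_truth_{positive,negative}.csv
#   sim/paradigm.yaml

suppressPackageStartupMessages(library(oisbold))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

paradigm <- make_paradigm()          # 60 s baseline, 30 x 16 s stim, ISI 70 s
regions <- list(positive_region(), negative_region())
tissue <- heterogeneous_tissue()     # the "true" cortex: surround response deep
optics <- optical_constants()

message("Paradigm: "); print(paradigm)

field <- trial_window_field(paradigm, regions, grid_px = c(64, 64))
message(sprintf("Trial-window field: %d frames at %g Hz, peak dHbT %+0.2f uM, trough %+0.2f uM",
                dim(field$d_hbt)[1], field$rate_hz,
                max(field$d_hbt), min(field$d_hbt)))

lut <- build_lut(tissue, optics, n_photons = 20000, seed = 1)
stack <- render_wavelength_stack(field, tissue, lut, optics,
                                 noise_sd = 2e-4 / sqrt(paradigm$n_trials),
                                 seed = 11)
message(sprintf("Rendered stack: attenuation range [%.4f, %.4f]",
                min(stack$attenuation), max(stack$attenuation)))

mr <- mr_config(n_protons = 10000, n_geom = 2, seed = 3)
blut <- build_bold_lut(mr)
base <- baseline_concentrations(tissue, optics)
field_fmri <- generate_haemodynamics(paradigm, regions,
                                     grid_px = c(64, 64), rate_hz = 1)
fmri <- generate_fmri(field_fmri, base, mr, blut, noise_sd = 0.005,
                      seed = 21, paradigm = paradigm)
message(sprintf("fMRI series: %d frames x %d x %d", dim(fmri$data)[1],
                dim(fmri$data)[2], dim(fmri$data)[3]))

write_region_csv(field, field$region_masks[[1]],
                 file.path(out, "region_series_truth_positive.csv"))
write_region_csv(field, field$region_masks[[2]],
                 file.path(out, "region_series_truth_negative.csv"))
write_paradigm_yaml(paradigm, file.path(out, "paradigm.yaml"))
saveRDS(field, file.path(out, "field_window.rds"))
saveRDS(stack, file.path(out, "stack.rds"))
saveRDS(fmri, file.path(out, "fmri.rds"))
saveRDS(list(lut_true = lut, blut = blut, mr = mr),
        file.path(out, "luts_true.rds"))
message("done: ", out)
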