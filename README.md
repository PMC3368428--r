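# oisbold

Can visible-light optical imaging of cortical haemodynamics account for the
BOLD fMRI signal it is measured alongside — including the *negative* BOLD
response in the cortex surrounding an activated region?  `oisbold` implements
the complete computational chain needed to ask that question on synthetic
data: forward simulation of two-dimensional optical imaging spectroscopy
(2D-OIS), spectroscopic inversion into haemoglobin maps, biophysical
prediction of the 7 T gradient-echo BOLD signal, and quantitative comparison
against a concurrently simulated EPI measurement.

It is written for imaging neuroscientists and methods developers who work
with concurrent optical/fMRI experiments in rodent somatosensory cortex, and
for anyone who needs a tested, self-contained reference implementation of
the individual stages.

## The models

**Photon transport and the modified Beer–Lambert relation.** Light at the
four filter bands (495 ± 31, 587 ± 9, 559 ± 16, 575 ± 14 nm) is propagated
through layered cortical tissue by Monte Carlo (Henyey–Greenstein
scattering, weight-deposition absorption, exact Russian-roulette
bookkeeping), giving the mean partial path length L_l(λ, μa) of remitted
photons in each layer, tabulated in a lookup table.  Attenuation changes
A(λ) = −ln(I/I₀) then obey

    A(λ) = Σ_l L_l(λ, μa_l) · w_l · [ε_HbO₂(λ) ΔHbO₂ + ε_Hbr(λ) ΔHbr]

and the **path-length scaling algorithm (PLSA)** inverts the four-band
system per pixel and frame by iterating path-length evaluation and a
2-unknown least-squares solve until the concentration estimate converges
(ΔHbT = ΔHbO₂ + ΔHbr exactly).  Two baseline tissue models are provided: a
homogeneous slab (6% blood volume ↔ 104 μM HbT, baseline saturation
Y₀ = 50%) and a five-layer heterogeneous model (6% above 1 mm, 4% below)
with greater sensitivity to deep cortical changes.

**Extravascular MR signal attenuation.** Vessels are randomly oriented
cylinders (radius bracketed 3–20 μm) in a periodic voxel with
susceptibility offset Δχ = 0.18 ppm(cgs) · Hct · (1 − Y); protons
random-walk outside them and dephase in the cylinder dipole field, giving

    ΔR2*(V, Y, r) = −ln[ S(V, Y) / S(V₀, Y₀) ] / TE,
    BOLD fraction = exp(−ΔR2*·TE) − 1

at B₀ = 7 T, TE = 12 ms.  State and baseline share random numbers, so the
baseline anchor ΔR2* = 0 is exact; one simulation per (V, r) yields all Y by
phase rescaling.

**Mapping and comparison.** Voxelwise GLM (boxcar response + ramp + DC,
two-pass design refinement), cluster thresholding (z > 4 positive, z < −2
negative, > 5 adjacent voxels), Gaussian smoothing (σ = 489 μm), Keys cubic
resampling, exhaustive scale/rotation/translation normalised
cross-correlation, and least-squares projective warping from ≥ 4 fiducial
points.

## Worked example

Render a noise-free four-wavelength stack from the default positive
(activated) region, invert it, and sweep the analysis baseline saturation:

```r
library(oisbold)

paradigm <- make_paradigm()             # 60 s baseline, 30 x 16 s stim, ISI 70 s
tissue   <- homogeneous_tissue()
optics   <- optical_constants()

field <- trial_window_field(paradigm, list(positive_region()),
                            grid_px = c(44, 44))
lut   <- build_lut(tissue, optics, n_photons = 20000, seed = 2)
stack <- render_wavelength_stack(field, tissue, lut, optics)

rec <- plsa_invert(stack, lut, baseline_concentrations(tissue, optics))
range(rec$d_hbr)                        # -2.9969  0.0000   (ground truth peak: -3 uM)

mr    <- mr_config(n_protons = 10000, n_geom = 2, seed = 3)
blut  <- build_bold_lut(mr)
sweep <- y0_sweep(stack, lut, tissue, optics, mr, blut,
                  mask = field$region_masks[[1]])
sweep$table
#>    y0 peak_abs_bold
#> 1 0.3        0.0156
#> 2 0.4        0.0172
#> 3 0.5        0.0177
#> 4 0.6        0.0168
#> 5 0.7        0.0142
#> 6 0.8        0.0101
#> 7 0.9        0.0047
sweep$argmax_y0                         # 0.5
```

The recovered deoxy-haemoglobin trace reproduces the ground truth to within
interpolation error, and the modelled BOLD magnitude peaks when the analysis
baseline saturation matches the true 50% — with little sensitivity across
the physiological 40–70% range.  The full analysis (both tissue models, GLM
mapping, spatial matching, Fig.-style prediction-vs-measurement regression)
is scripted under `analysis/`:

```sh
Rscript analysis/01_simulate.R      # synthetic optics + fMRI
Rscript analysis/02_photon_luts.R   # path-length lookup tables
Rscript analysis/03_invert.R        # PLSA, hom + het models
Rscript analysis/04_predict_bold.R  # extravascular BOLD + radius envelope
Rscript analysis/05_y0_sweep.R      # baseline-saturation sensitivity
Rscript analysis/06_glm_spatial.R   # z-maps, clusters, affine match
Rscript analysis/07_run_all.R       # one-shot end-to-end report
```

Outputs (CSV series, JSON reports, NIfTI maps) land under `results/`.  The
methods vignette (`vignettes/oisbold-methods.Rmd`) documents every model,
parameter and design choice.

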