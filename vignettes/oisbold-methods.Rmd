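---
title: "From optical imaging spectroscopy to predicted BOLD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From optical imaging spectroscopy to predicted BOLD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oisbold` links two ways of watching the same cortical haemodynamics: visible-light
two-dimensional optical imaging spectroscopy (2D-OIS) of the exposed rodent cortex,
which yields micromolar changes in oxy-, deoxy- and total haemoglobin
(ΔHbO₂, ΔHbr, ΔHbT = ΔHbO₂ + ΔHbr), and gradient-echo BOLD fMRI at 7 T, whose contrast
is driven by the paramagnetism of deoxy-haemoglobin.  The package implements the full
computational chain needed to test whether optical measurements can account for
concurrently measured positive *and negative* BOLD signals: a synthetic-data generator,
Monte Carlo photon transport through layered cortex, the path-length scaling inversion
(PLSA), a Monte Carlo model of extravascular MR signal attenuation around vessels, GLM
activation mapping, and spatial template correlation.  Everything runs on synthetic data
generated by the package itself; no animal data are shipped or required.

This vignette is the package's account of the science in each stage: the models, their
assumptions, the tunable parameters, and the choices made where the design was open.

## The synthetic study

The generator emulates a whisker-stimulation protocol: 60 s baseline, then 30
stimulation events of 16 s with a 70 s inter-stimulus interval; optics sampled at 8 Hz
per wavelength on an 80 µm grid, fMRI as a 64 × 64 matrix with FOV 30 mm and
TR/TE = 1000/12 ms.  Two disc regions carry trial-locked responses built from a
boxcar convolved with a gamma kernel, modulated by an exponential adaptation toward a
plateau:

* **positive region** (activated barrel cortex): ΔHbT peak +5 µM, ΔHbr −3 µM, peak at
  ~4 s with a plateau at 45% of peak, an early Hbr "deoxy dip" lobe (0.3 µM), and a
  post-stimulus Hbr undershoot (0.5 µM) that maps onto the ~1% BOLD overshoot the
  generator exposes as an optional lobe without taking a stance on its physiology;
* **negative region** (surround): ΔHbT −2.5 µM, ΔHbr +1.5 µM, slower (peak ~8 s),
  no biphasic dip — the deep-layer signature that produces sustained negative BOLD.

Peak amplitudes were chosen once to give BOLD excursions of roughly +2% and −0.5%,
the order observed in high-field rodent barrel cortex work.  Regions are discs with a
1-pixel-σ Gaussian edge taper (truncated 4 px out); the field is exactly zero outside.
HbO₂ is computed as HbT − Hbr so closure is exact by construction.  Each region also
carries a *depth profile* used by the forward optical model: the positive response is
placed superficially (0–1 mm), the negative response deep (1–2 mm), matching reports
that negative-BOLD haemodynamics peak near 1.3 mm.  Noise enters the chain where the
measurements live: Gaussian noise in the attenuation (log) domain for the optics,
fractional Gaussian noise per frame for the fMRI; the haemodynamic field itself is
deterministic unless asked otherwise.  What the generator does **not** emulate: vessel
anatomy (arteries vs parenchyma), physiological (cardiac/respiratory) noise, EPI
geometric distortion, and inter-animal variability.  Tests passing on this generator
therefore show the chain is self-consistent and correctly coded — not that it will fit
any particular animal.

## Photon transport and the path-length LuT

Light transport through the cortex is simulated with a layered-slab Monte Carlo
(hop/drop/spin): step lengths sampled against the total attenuation µt = µa + µs of the
current layer, a fraction µa/µt of the photon weight deposited at each interaction, and
scattering directions drawn from the Henyey–Greenstein phase function.  Photons crossing
the surface upward are *remitted* and score the path they travelled in each layer.
Because the imaging well is fluid-filled, the surface is treated as refractive-index
matched (no internal reflection).  Russian roulette (cutoff 10⁻⁴, survival 0.1) is
bookkept exactly: kills credit the absorbed bucket and survivor boosts debit it, so
remitted + absorbed + transmitted equals the launched weight to numerical precision —
a property the tests assert at 10⁻⁹.

Two stock tissue models are provided. The homogeneous model is a single slab with 6%
blood volume (tissue HbT 104 µM at the default whole-blood concentration of 1733 µM —
a number implied by the 6% ↔ 104 µM anchor and exposed as configuration).  The
heterogeneous model has five layers (boundaries 0.3/0.6/1/2/10 mm) with 6% blood volume
above 1 mm and 4% below.  Scattering defaults to µs = 20 mm⁻¹ with g = 0.9
(µs′ = 2 mm⁻¹), a standard grey-matter figure; background absorption 0.02 mm⁻¹.  All are
configurable — they are explicit stand-ins where the source material defers to its
references.

Mean partial path lengths per layer are tabulated over the four filter bands
(495 ± 31, 587 ± 9, 559 ± 16, 575 ± 14 nm; centre-wavelength treatment) and an
absorption grid of 10 nodes spanning 0.03–4 mm⁻¹.  Baseline band absorptions sit at
0.45–1.25 mm⁻¹, so the grid covers every physiological excursion with margin; lookups
interpolate linearly and refuse to extrapolate.  The Monte Carlo was checked against an
independently coded diffusion-approximation differential-pathlength oracle (plane
isotropic source at one transport mean free path, extrapolated boundary): at
µs′ = 1 mm⁻¹, µa = 0.01 mm⁻¹ the two agree within ~7%, inside the 15% band expected of
diffusion theory in that regime.

Haemoglobin extinction spectra are shipped as a plain-text table of base-10 molar
extinction anchors (450–650 nm) compiled approximately from the standard published
compilations, with the characteristic HbO₂ double peak (542/577 nm), the Hbr single
peak (555 nm) and the isosbestic points near 500/522/548/569/586 nm; a monotone spline
interpolates between anchors.  The forward renderer and the inversion share this table,
so round-trip accuracy does not depend on its absolute calibration — but absolute µa
values (and hence path lengths) do, at the ~10–20% level of the transcription.

## The PLSA inversion

The measured quantity is attenuation change A(λ,t,x,y) = −ln(I/I₀).  The model is the
modified Beer–Lambert relation with layer-resolved path lengths:

A(λ) = Σₗ Lₗ(λ, µa,ₗ) · wₗ · [ε_HbO₂(λ) ΔHbO₂ + ε_Hbr(λ) ΔHbr]

Per pixel and frame the algorithm iterates: evaluate each layer's µa at the current
concentration estimate, look up Lₗ, solve the 4-band × 2-chromophore system by least
squares (closed-form 2 × 2 normal equations, vectorised over pixels), and repeat until
the update falls below 10⁻³ µM or 50 iterations (non-converged pixels are flagged and
keep their final iterate; the residual norm is stored per pixel for QC).  In practice
noise-free stacks converge in 1–2 iterations because the path lengths vary slowly with
µa.

The layer weighting wₗ is the genuinely open design point.  The default is
partial-path-length proportional weighting (wₗ = Lₗ/ΣL, re-evaluated each iteration),
which makes the effective path of a multi-layer model ΣL²/ΣL < ΣL — shorter than the
homogeneous slab's total path — so the heterogeneous analysis recovers *larger*
haemodynamic magnitudes, proportionally more so for deep changes.  An explicit weight
vector can be supplied instead (e.g. a deep prior when one knows the response is deep).
When evaluating perturbed absorptions the concentration change is distributed over
layers with static weights computed from baseline path lengths, which reduces exactly
to µa₀ + Δµa for the homogeneous slab; round trips on the homogeneous model are then
exact to interpolation error, and the 5% recovery criterion is met with orders of
magnitude to spare.

Two caveats follow from the model and are visible in the end-to-end run.  First, with
the default weighting neither analysis recovers a strictly deep change at full
magnitude — green-light partial paths below 1 mm are small, so both models
under-estimate the surround response and the heterogeneous one simply under-estimates
it least; with so little deep attenuation the four-band least-squares solve can even
mis-assign the residual signal between the two chromophores, though the predicted BOLD
sign survives through the combined volume and oxygenation terms.  The end-to-end ordering (heterogeneous gradient closer to 1) is what the
chain reproduces; the absolute gradients stay below 1 for the synthetic deep-only
surround, unlike a real cortex where the response is distributed in depth.  Second, the
analysis-model effect is almost purely a rescaling: recovered time courses under the two
models correlate above 0.95.

## Baseline saturation

Baseline oxygen saturation Y₀ enters both the spectroscopic baseline (via µa₀) and the
MR baseline state.  The default Y₀ = 50% corresponds, through the rat Hill dissociation
curve (p50 = 38 mmHg, n = 2.6), to the ~40 mmHg oxygen tension measured in rat
parenchyma: S(40) = 40^2.6/(40^2.6 + 38^2.6) = 0.533 ≈ 50%.  `y0_sweep()` re-analyses
the same stack at Y₀ = 30–90%: rebuild the baseline, invert, predict BOLD at the
mid-range radius, and score the peak absolute region-mean change.  On the default
synthetic positive-region stack the modelled BOLD magnitude peaks at Y₀ = 50% and
the 40–70% values span only ~20% of their mean — the low-Y₀ side is suppressed because a
more deoxygenated baseline sits further up the (supralinear at small δω·TE) dephasing
curve *and* mis-scales the inversion, while the high-Y₀ side loses signal as the
baseline deoxy-haemoglobin pool shrinks.

## MR signal attenuation

The BOLD forward model is a Monte Carlo of extravascular dephasing: vessels are
infinite cylinders of one radius with random positions and orientations in a periodic
cube (16 cylinders; the cube edge is set from the target volume fraction, ≥ 20 radii),
carrying a susceptibility offset Δχ = 0.18 ppm (cgs) × Hct(0.4) × (1 − Y).  Protons
random-walk outside the cylinders (D = 10⁻⁹ m²/s, dt = 0.2 ms) and accrue phase from
the classic cylinder dipole field; steps into a vessel are elastically reflected
(disabling reflection changes ΔR2* by under 5% at 6% blood volume).  The signal is the
magnitude of the mean phasor at TE, and
ΔR2* = −ln(S(V,Y)/S(V₀,Y₀))/TE with the baseline simulated under identical random
numbers, so the baseline anchor ΔR2* = 0 is exact.  The susceptibility scale factors
out of the walk, so one simulation per (V, r) yields every Y by phase rescaling —
exact, and an order of magnitude cheaper when building the (V, Y, r) lookup table
(default 11 × 23 × {3, 10, 20 µm} nodes; trilinear access with baseline subtraction).
Geometry and walk seeds are shared across V, Y *and* radius, so comparisons along any
table axis are common-random-number comparisons; marginal values remain valid Monte
Carlo estimates.

Model checks: ΔR2* at 50 µm agrees with an independently coded static-dephasing oracle
(no diffusion, numerical orientation/position average) within a few percent once both
are averaged over enough geometries (per-geometry scatter is ~10%); the gradient-echo
response is non-decreasing over 3–20 µm and ΔR2*(20 µm) sits within 10% of
ΔR2*(15 µm) — the plateau that justifies capping the radius envelope at 20 µm; and over
the physiological range ΔR2* is close to linear in (1 − Y)·V (R² > 0.95).

BOLD fractions use exp(−ΔR2*·TE) − 1 rather than the linearisation; predictions are
evaluated at radii {3, 10, 20} µm, reported as an envelope [elementwise min, max]
around the 10 µm central curve.  The mapping from micromolar fields is
V = V₀(HbT₀+ΔHbT)/HbT₀ and Y = (HbO₂₀+ΔHbO₂)/(HbT₀+ΔHbT), clipped to [0, 1] with a QC
counter.  The intravascular compartment is excluded by design: predictions are of the
extravascular space, and the ~7% intravascular contribution reported for small vessels
at 7 T is documented here rather than simulated.

## GLM mapping and spatial comparison

Activation mapping follows the fixed-threshold convention: a three-column design
(trial-locked boxcar response, ramp, DC), ordinary least squares per voxel,
z = β/SE(β), and cluster thresholding that keeps components of more than five adjacent
voxels (size ≥ 6; configurable, 4-connectivity by default) above z = 4 for positive and
below z = −2 for negative BOLD.  No autocorrelation correction is applied — with
trial-averaged series none was needed.  Mapping is two-pass: preliminary boxcar maps
select peak regions, whose mean time series (detrended, unit-peak) replaces the
response column before the final fit.  Whether the "boxcar response function" should be
kernel-convolved is left open upstream; both are supported and the plain boxcar is the
default.  fMRI series are cubic-interpolated to 8 Hz before comparison with optical
predictions.

Spatial concordance uses: Gaussian smoothing of the fMRI parameter map
(σ = 489 µm, the FOV-scale voxel; reflective boundaries, unit-sum kernel), Keys
bicubic subsampling (a = −0.5, exact for quadratics), and exhaustive normalised
cross-correlation over uniform scale (0.10–0.25, step 0.01), rotation (±15°, step 1°)
and integer translation, with masked correlation so rotated-template corners do not
bias the score.  The optics-to-fMRI resolution ratio implies a true scale of
80/468.75 ≈ 0.17; the search grid brackets it.  On synthetic runs the recovered scale
can sit a few grid steps high when the smoothed blobs are small — the correlation
surface is shallow in the scale direction, a limitation worth knowing before reading
much into the exact scale.  Fiducial-based projective warping (DLT, least squares for
> 4 points, exact for 4) with inverse-mapped bilinear resampling supports the
histology-style section-to-section registration; compositions of exact fits agree with
direct fits to 10⁻⁶ px.

## Numerical choices and problem sizes

Coordinates are 0-based pixel centres, row-major (y, x); homography points are (x, y).
The trial-collapsed optical stack is analysed over a single 70 s window (with
noise-free generation every trial is identical, so one window equals the trial
average; its noise is scaled by 1/√30).  The analysis scripts and tests run at reduced
Monte Carlo sizes chosen to keep every statistical criterion several standard errors
clear of its bound: photon LuTs at 10⁴–2×10⁴ photons per node, dephasing runs at
3–10 × 10³ protons with 2–10 geometry realisations, fields on 44–64 px grids.  The
defaults in the package are the study-scale values; nothing in the physics changes with
size.

## Known limitations

* The extinction table is an approximate transcription; absolute concentrations are
  accurate only to its calibration, though all self-consistent (render → invert)
  results are exact by construction.
* One analysis weighting cannot recover both a superficial and a strictly deep change
  at unit gradient; the chain reproduces the tissue-model *ordering*, not gradient
  values near 1, for the deep-only synthetic surround.
* The dephasing model uses a single vessel radius per evaluation, a periodic
  minimum-image geometry, and no intravascular signal, inflow, or spin-echo variant.
* Template matching has no sub-pixel refinement by default and its scale estimate is
  soft for small, smooth maps.
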