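---
title: "SLIM-based lipid removal for deuterium metabolic imaging: models, parameters and validation"
author: "dmislim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SLIM-based lipid removal: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deuterium metabolic imaging (DMI) maps deuterated glucose and its
metabolic products (glutamate/glutamine, lactate) across the brain with
coarse phase-encoded spectroscopic imaging. Natural-abundance ^2^H lipid
signals from the skull and scalp share the lactate chemical shift
(~1.3 ppm), so extracranial lipid contaminates exactly the resonance that
carries the clinical signal, producing artifactual hot spots in
Lac/(Lac+Glx) maps. Because anatomical MRI cleanly separates brain from
non-brain at high resolution, the contamination can be removed in
post-processing from spatial prior knowledge alone, without touching the
simple pulse-acquire DMI acquisition.

`dmislim` implements this removal with the SLIM (spectral localization by
imaging) compartmental model, extended with two robustness mechanisms —
subdivision of the extracranial compartment and B0/B1 field compensation —
plus a complete synthetic-phantom framework used to validate every stage.

## The compartmental model

Phase-encoded MRSI measures, for encoding $m$ and time $t$,

$$P[m,t] \;=\; \sum_{k=1}^{N_\mathrm{ROI}} G[m,k]\, C[k,t],
\qquad
G[m,k] \;=\; \int_{\mathrm{ROI}_k} e^{\,i 2\pi \mathbf{k}_m \cdot \mathbf{r}}\, d\mathbf{r},$$

where $P$ is the $N_\mathrm{enc}\times N_\mathrm{time}$ k-space data
matrix, $C$ holds one time-domain signal per compartment, and the
compartments (from segmented MRI) partition the object. With
$N_\mathrm{ROI} \le N_\mathrm{enc}$, $C = G^{+} P$ via a singular-value
decomposition pseudoinverse (`slim_invert()`; singular values below
`svd_tol` times the largest are truncated, default $10^{-10}$ — the
inversion is deliberately unregularized, and rank deficiency at that
tolerance is an error rather than a silent truncation). A skull-only
dataset $P_\mathrm{skull} = G_\mathrm{skull} C_\mathrm{skull}$ is then
reconstructed and subtracted from the measured data
(`reconstruct_subset()`, `remove_skull()`), yielding a lipid-free dataset
while brain signals pass through *untouched except for the subtraction* —
the central robustness property of the approach.

The ROI integral is discretized as a pixel-center Riemann sum on the
MRI-resolution raster (an integer upsampling of the MRSI grid, default 6
pixels per 20 mm voxel axis), with the $+i2\pi$ phase convention in the
encoding and its conjugate in FFT reconstruction; a round-trip test pins
the convention.

If every compartment is internally homogeneous the separation is exact.
Real compartments are not: B0 offsets (water line shifts, in Hz) and
receive-sensitivity variation (relative B1) vary across each compartment.
Two mechanisms address this:

1. **Skull subdivision** (`subdivide_skull()`): the extracranial ROI is
   multiplied by an equidistant grid (`grid_mm`, default 20 mm) and
   sub-ROIs below a minimum volume (default 40% of the nominal MRSI
   voxel) are merged into the adjacent sub-ROI with the nearest centroid
   (ties to the lowest label; disconnected fragments merge by centroid
   distance alone). Smaller sub-ROIs are individually more homogeneous.
2. **Field-augmented encoding** (`build_field_encoding()`):
   $$G[m,k](t) = \int_{\mathrm{ROI}_k} B_1(\mathbf{r})\,
     e^{\,i2\pi B_0(\mathbf{r}) t}\, e^{\,i2\pi \mathbf{k}_m \cdot \mathbf{r}}\, d\mathbf{r},$$
   inverted per time point (512 small pseudoinverses). A single
   multiplicative receive-sensitivity factor is used for B1; transmit
   effects are not modeled separately. With the *exact* fields this
   restores perfect separation; in practice surrogate maps are estimated
   from the DMI data itself.

### Choosing the number of skull sub-ROIs

Subdivision has a cost, quantified by the spatial response function

$$\mathrm{SRF}_k(\mathbf{r}) = \sum_m G^{+}[k,m]\, e^{\,i2\pi \mathbf{k}_m \cdot \mathbf{r}},$$

whose phase-sensitive integral is 1 over the compartment's own ROI and 0
over every other (an algebraic identity tested to $10^{-6}$ for
$N_\mathrm{skull} \in \{1, 10, 23, 44\}$). As sub-ROIs shrink below the
k-space resolution, the *absolute-valued* SRF inside the brain grows and
localization increasingly relies on phase cancelation
(`brain_leakage()`), which heterogeneity breaks: lipid suppression keeps
improving with $N_\mathrm{skull}$, but metabolite retention becomes
volatile beyond roughly 35 sub-ROIs on a 9×13 grid. A moderate
subdivision (sub-ROI counts in the low twenties, or simply a grid of
nominal DMI voxels) combined with field compensation is the recommended
operating point.

### Surrogate field maps

High-resolution ^2^H field maps are not measurable at DMI sensitivity, so
surrogates come from the water line of the DMI data itself
(`estimate_surrogate_maps()`): per voxel, the water peak position
(3-point parabolic interpolation of the magnitude spectrum within a
±30 Hz window; the estimator is not prescribed by the method, parabolic
interpolation is this package's choice) gives B0 in Hz, and the
integrated water magnitude gives relative B1. Because edge voxels are
only partially filled by the object, the B1 integral is divided by the
voxel's object partial-volume fraction computed from the ROI prior —
information the method has by construction; voxels under 25% object
fraction are flagged missing. Both maps are normalized (B1 to maximum 1,
matching the relative 0.15–1.00 in-vivo range) and parameterized by a 2D
polynomial least-squares fit (order 3 by default; order 4 supported)
evaluated at the MRI raster, which simultaneously denoises and upsamples
them. Fitted B1 surfaces are floored at 0.02 inside the object so the
augmented encoding remains valid where a low-order polynomial
undershoots.

## The synthetic validation framework

`make_head_phantom()` builds a parametric 2D head at MRI-like resolution:
an elliptical brain (nominal semi-axes 56 × 85 mm, randomized ±~8% per
seed) with CSF rim, central ventricle, GM shell and WM core; a closed
extracranial annulus ("skull", nominal thickness 22 ± 2 mm, representing
skull plus scalp); and one pathology region of random superellipse shape,
its area drawn uniformly in 72%–148% of the nominal voxel area, placed
fully inside the brain with bounded retries. The annulus thickness was
set so that the annulus holds up to ~50 sub-ROIs above the 40%
minimum-volume threshold on the 9 × 13 × (20 mm)² grid — the regime the
subdivision study explores; this makes the annulus thicker than a
literal skull, and it should be read as the whole extracranial tissue
layer.

Signals are Lorentzian: each compartment carries one well-resolved line
plus a water line common to all compartments, $T_2 = 30$ ms (10.6 Hz
FWHM), equal amplitude per unit volume, 512 complex points over 1.0 kHz.
Synthetic line offsets (water 0, brain metabolite −180 Hz, lipid
−380 Hz; tissue-specific variants at −120…−300 Hz) are chosen well
separated relative to the linewidth; they are not the in-vivo chemical
shifts, for which `invivo_bands()` provides the ppm-based defaults.
Optional circular complex Gaussian noise is added to the full
$N_\mathrm{enc} \times N_\mathrm{time}$ matrix.

Random B0 fields are order-4 2D polynomials with i.i.d. uniform
coefficients, affinely rescaled so their min/max over the object equal
−10 and +10 Hz — the shape is random, the physiological range is
guaranteed. For B1 a purely random surface is not physical: measured
relative ^2^H-water intensity maps reflect a close-fitting receive
array — low in the center of the brain (0.15) and high near the
periphery (1.00), with the rim gradient smoothed by voxel averaging and
polynomial parameterization. The generator therefore blends a radial
profile $2\rho^2-\rho^4$ (rising from the center, plateauing at the rim;
still a polynomial) with a random polynomial at weight 0.75 : 0.25
before rescaling to 0.15–1.00. This structure matters: with it, B0
heterogeneity dominates the uncompensated residual (compensating B0
alone helps ~3×, B1 alone ~1×), skull suppression increases
monotonically with subdivision, and the retention volatility beyond ~35
sub-ROIs appears — the qualitative signature of the reference
simulations. With a purely random B1 the importance ordering inverts.

### Metrics

Analysis is by numerical band integration of magnitude spectra after
standard FFT reconstruction (`suppression_percent()`,
`retention_percent()`). Suppression is evaluated per skull-containing
voxel as $100(1 - \text{lipid after}/\text{lipid before})$, retention per
pure-brain voxel (voxel classes by pixel counting at MRI resolution);
partial-skull voxels are included in suppression even though they bias it
low. Magnitude-spectrum Lorentzian tails decay only as $1/\Delta f$, so
even a perfect reconstruction cannot reach exactly 100% on the plain
before/after ratio (brain-line tails remain in the lipid band). In
simulations, where the ground-truth brain-only and skull-only datasets
exist, both metrics accept a `reference` dataset and integrate
complex-difference spectra, quantifying the skull signal itself; with
homogeneous compartments these metrics are exactly 100% to machine
precision, which is the form of the exactness statement this package
tests. Both aggregations (per-voxel mean and amplitude-weighted) are
recorded; the per-voxel mean is the primary statistic.

For in-vivo-style spectra without ground truth, `fit_lorentzians()`
offers time-domain Levenberg–Marquardt fitting of damped complex
sinusoids with metabolite linewidths optionally bounded to the water
linewidth ± a configurable window (the reference processing constrains
linewidths relative to water but does not state the window; it is a
parameter here, with the water line pre-fit anchoring the bounds).

### The two simulation studies

`run_fig2(n_datasets = 50)` sweeps removal conditions over 50 random
phantoms with unique fields, paired across conditions through seeded
substreams: no heterogeneity, exact-field compensation, a single skull
ROI with and without surrogate-map compensation (also B0-only and
B1-only), and subdivision bands 20–28 / 29–36 / 37–48. At the defaults
(n = 50, seed 1) this package obtains, for lipid suppression:
~49% (N~skull~ = 1, uncompensated; reference 47 ± 21), ~87%
(surrogate compensation; reference 92 ± 6), and 81 / 88 / 88% across the
subdivision bands (reference 90 ± 12, 97 ± 3, 99 ± 1), with
residual-reduction factors ~4.0× (combined), ~3.4× (B0-only), ~1.0×
(B1-only) against reference 6.6× / 2.9× / 1.1×. Retention stays at
100.0 ± ~0.4%. The means at N~skull~ = 1 and under compensation, the
reduction-factor ordering, and all qualitative trends reproduce; the
subdivided-band suppression plateaus several points below the reference
values and the across-dataset retention variability (~0.4% vs ~3%) is an
order of magnitude smaller. Both gaps have the same plausible origin:
smooth elliptical compartments with low-order polynomial fields carry
less fine-scale heterogeneity and less irregular compartment geometry
than real segmented heads, so sub-ROI mismatch and SRF-leakage
variability are both understated. The generator was frozen with the
physically motivated structure above; these two quantities are reported
as-is rather than tuned toward the reference values.

`run_fig3()` studies partial-volume robustness: a fixed brain + tumor +
skull constellation (the tumor carries lactate and a tumor-specific
reference line at equal amplitude per unit volume, so an ideal lipid-free
dataset has a lactate-to-reference ratio of exactly 1) is shifted
relative to the MRSI grid until a tracked voxel's pixel-counted skull
fraction hits 10%–70% (12× upsampling for fine fraction steps; shifts
that would put air into the tracked voxel are excluded; unreachable
fractions are skipped with a warning). Over 20 random field draws per
fraction, standard FFT processing inflates the ratio monotonically
(~1.25 → ~2.8) as lipid enters the voxel; SLIM with N~skull~ ≈ 23 holds
it at 0.99–1.01 across all fractions; a single skull ROI degrades beyond
~40% partial volume. These match the reference behavior, including the
stability band of 1.00 ± 0.05.

## Numerical and degenerate-input policy

* SVD truncation at `svd_tol` = 1e−10 (relative); deficient rank errors,
  listing the singular values.
* Field sampling resamples (next substream, with a warning) on a
  degenerate constant surface; the affine rescale guarantees exact range
  endpoints.
* Pathology placement and fraction targeting use bounded retries/scans
  and fail loudly (placement) or skip with a warning (unreachable
  fraction).
* Merging is deterministic: smallest under-threshold sub-ROI first, ties
  by lowest label, nearest-centroid target.
* Suppression excludes voxels whose before-integral is numerically zero;
  retention requires at least one evaluable pure-brain voxel.
* Zero spectra fit to zero amplitudes; non-convergence of a spectral fit
  flags the voxel rather than erroring.

## Problem sizes

Default study sizes are those of the reference simulations — 50 datasets
for the condition sweep, 20 field draws per partial-volume point, 9 × 13
encodings, 512 time points — and run in a few minutes on a single core;
unit tests use a reduced 5 × 7 grid with 4× upsampling. The MRI raster
upsampling factor (6) trades partial-volume fidelity against cost;
results are insensitive to raising it.

## What passing simulations do and do not show

The phantom framework validates the algebra (exactness limits at machine
precision, SRF identities, oracle-checked inversion), the end-to-end
pipeline, and the qualitative response to field heterogeneity,
subdivision and partial volume. It does not validate segmentation
accuracy, MRI↔DMI co-registration or motion (masks are inputs and assumed
exact), realistic noise and lineshape distortions (simulations here are
noiseless unless requested), 3D acquisitions (the spherical k-space
scheme is implemented, but the validated pipelines are 2D, as in the
reference simulations), or the in-vivo statistics, which require the
externally hosted measured dataset (see
`inst/scripts/invivo_validation.R` for the documented optional
procedure).
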