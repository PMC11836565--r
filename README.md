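# dmislim

SLIM-based removal of extracranial lipid signals from deuterium metabolic
imaging (DMI) data, using spatial prior knowledge from anatomical MRI.

## The problem

DMI maps deuterated glucose and its metabolic products across the human
brain with coarse 3D phase-encoded spectroscopic imaging. Natural-abundance
²H lipid signals from the skull and scalp overlap the lactate resonance
(~1.3 ppm), contaminating exactly the signal that distinguishes aberrant
(Warburg) tumor metabolism in Lac/(Lac+Glx) maps. Because anatomical MRI
separates brain from non-brain at high resolution, the lipid signal can be
removed in post-processing without modifying the simple DMI acquisition.

`dmislim` is aimed at MRS(I) methods researchers: it implements the full
removal workflow and a synthetic-phantom framework that validates every
stage without measured data.

## The method

Phase-encoded MRSI is modeled as **P = G C**, with **P** the measured
N_enc × N_time k-space matrix, **C** the per-compartment time signals, and
the encoding matrix

    G[m, k] = ∫_ROI_k exp(i 2π k_m · r) dr

computed from MRI-derived compartment masks. **C = G⁺P** via a truncated-SVD
pseudoinverse; the skull compartments' contribution **G_skull C_skull** is
reconstructed and subtracted, leaving a lipid-free dataset with brain
signals untouched. Compartment heterogeneity (B0 line shifts, B1 receive
sensitivity) is handled by (1) subdividing the skull ROI on an equidistant
grid with minimum-volume merging and (2) a field-augmented encoding

    G[m, k](t) = ∫_ROI_k B1(r) exp(i 2π B0(r) t) exp(i 2π k_m · r) dr

using surrogate B0/B1 maps estimated from the per-voxel ²H water line shift
and intensity of the DMI data itself, parameterized by low-order 2D
polynomial fits. Spatial response functions (SRF) diagnose how finely the
skull can be subdivided before localization starts to rely on phase
cancelation. See the methods vignette
(`vignettes/lipid-removal-methods.Rmd`) for models, parameters and design
choices.

## Worked example

Simulate a head phantom with random B0/B1 heterogeneity and remove its
extracranial signal with skull subdivision plus surrogate-map compensation:

```r
library(dmislim)

rois <- make_head_phantom(seed = 42)          # brain/skull/pathology labels
b0   <- sample_random_field("B0", order = 4, range = c(-10, 10),
                            rois = rois, seed = 43)           # Hz
b1   <- sample_random_field("B1", order = 4, range = c(0.15, 1),
                            rois = rois, seed = 44)           # relative
traj <- build_trajectory(rois$grid_dims, rois$fov_mm)
P    <- synthesize_dmi(rois, lipid_phantom_model(rois), traj,
                       b0 = b0, b1 = b1)      # 117 encodings x 512 points

cfg <- pipeline_config(n_skull_range = c(20, 28), compensation = "surrogate")
out <- run_pipeline(cfg, P, rois)
```

This prints (via the summaries below):

```
<roi_map> raster 54x78, MRSI grid 9x13, voxel 20x20 mm
  5 compartments, 2384 object pixels; roles: GM, WM, CSF, brain, skull, pathology
<kspace_data> 117 encodings x 512 points, sw = 1000 Hz, scheme full_cartesian
N_skull = 20, condition number = 47.8
lipid suppression: 86.9 +/- 25.8 % over 56 skull voxels
metabolite retention: 100.2 +/- 2.0 % over 27 pure-brain voxels
```

The skull ROI was subdivided into 20 sub-compartments; the lipid band
integral in skull-containing voxels dropped by 86.9% on average (partial
voxels included, which biases the estimate low), while the metabolite band
in pure-brain voxels is preserved at 100%. `out$lipid_free` and
`out$skull` hold the subtracted and skull-only k-space datasets;
`run_fig2()` and `run_fig3()` drive the full Monte-Carlo suppression/
retention sweep and the partial-volume lactate study, and
`inst/cli/dmi-slim.R` exposes the stages as a command line.

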