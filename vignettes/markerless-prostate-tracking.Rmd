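---
title: "Markerless prostate tracking in kV projections: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless prostate tracking in kV projections: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvtrack)
```

## The problem

During arc radiotherapy the prostate moves while the gantry rotates. The
on-board kilovoltage (kV) imager sees a 2D projection of the pelvis at every
gantry angle, but the prostate itself has almost no radiographic contrast, so
clinics implant gold fiducial markers as surrogates. A markerless
alternative trains a *patient-specific* image-to-image network before
treatment: the patient's planning volume and prostate contour are
forward-projected into paired (anatomy DRR, prostate-mask projection) images
over the full arc, a conditional GAN learns the mapping, and during treatment
the generator segments each incoming kV frame; the centroid of the largest
connected region of the binarised prediction is the tracked position.

`kvtrack` implements that pipeline end to end against a synthetic
digital-pelvis phantom with analytically known geometry, so every stage can
be verified offline without clinical data.

## Geometry and the shift mapping

Patient coordinates: x lateral, y superior-inferior (SI), z
anterior-posterior (AP), isocentre at the origin. At gantry angle
$\theta$ the x-ray source sits at $SAD\,(\cos\theta, 0, \sin\theta)$ and the
detector plane lies $SID$ from the source, perpendicular to the beam axis,
with in-plane axes $e_u = (\sin\theta, 0, -\cos\theta)$ (transverse) and
$e_v = (0,1,0)$ (SI). A 3D displacement $(\hat x, \hat y, \hat z)$ mm
projects to detector-plane coordinates

$$(\hat u, \hat v) = \frac{SID}{SAD - (\hat x\cos\theta + \hat z\sin\theta)}
  \,\bigl(\hat x\sin\theta - \hat z\cos\theta,\; \hat y\bigr),$$

implemented in `project_shift()`. Two consequences anchor the test suite:
motion along the beam axis is invisible, and small in-plane motion is
magnified by $M = SID/SAD$ (1.5 for the standard 1000/1500 mm setup, which
together with a 0.39 mm detector pixel gives the 0.26 mm isocentre pixel
used to report errors in patient coordinates, `pixel_to_isocentre_mm()`).

A note on naming: some descriptions of this geometry swap the long forms of
SAD and SID. Here SAD is always source-axis (isocentre) and SID
source-imager; this is the only reading under which the shift mapping's
denominator and the 1.5 correction factor are mutually consistent.

### Projector

`forward_project()` computes each pixel as the line integral of attenuation
along the source-to-pixel ray by uniform-step trilinear sampling, with step
`min(voxel spacing)/2` (midpoint rule over the ray-box intersection). That
flavour of DRR algorithm was chosen because it is simple and directly
checkable against an independent dense integrator, which the tests do on
randomly drawn rays (< 2% relative error). Linearity, non-negativity,
periodicity in $\theta$, and rotation equivariance (a volume rotated by
$\varphi$ about the SI axis projects at $\theta$ like the original at
$\theta - \varphi$) are tested as properties.

## The phantom

`phantom_spec()` describes ellipsoids on a voxel grid: a soft-tissue body,
higher-attenuation bones (femoral heads, a sacrum stand-in), an ellipsoidal
prostate, and optional spherical markers (field-standard cylindrical seeds
are simplified to spheres: orientation is irrelevant to the masking and
inpainting logic the phantom exists to exercise). Attenuations are arbitrary
consistent mm^-1 units; only line integrals matter, so no Hounsfield
calibration is attempted. Mild seeded Gaussian texture (SD 2% of the
soft-tissue value, clipped at zero) prevents the network from memorising
flat regions. The contour volume is exactly the set of voxels whose centres
lie inside the prostate ellipsoid, so its voxel count converges to the
analytic ellipsoid volume as spacing shrinks - one of the phantom's oracle
tests.

**The prostate is deliberately visible.** The default prostate attenuation
(0.045 mm^-1 vs 0.020 soft tissue) is far above anything anatomically
plausible; in real kV images the prostate is essentially invisible and a
clinical model must infer position from surrounding context. The phantom's
elevated contrast makes the desk-scale learning problem well-posed in
minutes of CPU time. Passing the end-to-end check therefore demonstrates
that the pipeline's machinery - projection, pairing, training dynamics,
inference, geometry, and evaluation - is correct and self-consistent; it
says nothing about segmentation accuracy on clinical images, which in the
source setting requires hours of GPU training on 36,000 full-resolution
pairs per patient.

The default prostate centre is off-isocentre (`c(5, 8, -6)` mm) so the
projected mask position varies with gantry angle; a model that memorised a
single fixed ellipse would fail the held-out-angle check.

## Training-set synthesis

`build_training_set()` applies each sampled rigid transform (components
uniform in ±10 mm and ±10°, the standard setup-error envelope; rotations
about the isocentre in x→y→z order) to the planning volume *and* contour,
then projects a full arc of both. At the paper-scale settings - 1° steps and
100 augmentations - this yields 360 images per volume and 36,000 pairs; the
desk-scale default is 45° steps and 8 augmentations (64 pairs). Anatomy
images are min-max normalised to [0, 1] *jointly over the set* (not per
image) so inter-angle intensity relationships survive; the range is stored
in the manifest and reused verbatim at inference. Mask projections are
binarised where the projected contour path length exceeds 0.1 mm, which
suppresses trilinear interpolation fringe. Deformable augmentation is
deliberately excluded (rigid-only augmentation is the established choice
for this pipeline). Large sets can be streamed to float32 shards on disk
instead of held in memory.

## The conditional GAN

The generator is a UNet: 4×4 stride-2 convolutions down, the mirror
transposed convolutions up, skip connections at every level, LeakyReLU(0.2)
encoder and ReLU decoder activations, sigmoid output bounded in [0, 1].
The discriminator is a PatchGAN scoring overlapping patches of the
(input, mask) pair; its grid is strictly smaller than the image. Channel
widths double per level from `base_channels` (default 16), capped at 8×.
Non-affine instance normalisation is applied on inner layers (`normalization
= "none"` disables it), and weights start from N(0, 0.02²) (`init = "he"`
selects fan-in-scaled initialisation instead). The objective is

$$G^* = \arg\min_G \max_D \; \mathcal L_{cGAN}(G, D) + \lambda\,\mathcal L_{L1}(G),
\qquad \lambda = 100,$$

with the usual log-likelihood discriminator term and the generator trained
in the standard non-saturating form ($-\log D(x, G(x))$ rather than the
literal min-max) - universal practice for this model family and numerically
necessary. Scores at exactly 0 or 1 are clamped at $10^{-7}$. Closed forms
anchor the tests: with $D \equiv 1/2$ and $y = G(x)$, $loss_D = 2\ln 2$ and
the generator adversarial term is $\ln 2$. The whole engine (im2col/GEMM
convolutions, hand-derived backprop, Adam) is implemented in compact
RcppArmadillo and verified against finite differences to ~1e-7 relative
error; with $\lambda$ dominant the generator update direction coincides
with pure-L1 regression (cosine > 0.99), separating the two loss paths.

Training (`train_patient_model()`) alternates discriminator and generator
Adam updates per mini-batch. Defaults follow the established recipe - 20
epochs, batch 4, learning rate 2e-4, Adam moments (0.5, 0.999) - and are
fully deterministic given the seed (all randomness flows through R's RNG).
No label flipping, instance noise, or learning-rate decay is used.

### A training-dynamics caveat worth knowing

An L1 loss against exactly-binary targets combined with a bounded sigmoid
output exerts a *permanent* downward force on every background pixel (the
output can never reach exactly 0), while the foreground force acts on few
pixels through shared convolution weights. At small scales this makes the
empty segmentation a strong attractor: in controlled experiments, targets
covering under ~5% of the frame never escaped it within thousands of Adam
steps, while targets covering ≥ ~13% trained to DSC ≈ 0.95 within 400
steps. The desk-scale defaults therefore use a 2 mm detector pitch, whose
~85 mm isocentre field the projected prostate fills to roughly the same
fraction (~20%) as in the full-scale clinical geometry (a ~133 mm field) -
the scaled-down problem then mirrors the full-scale one in the proportion
that matters for these dynamics.

## Inference and tracking

`segment()` thresholds the generator output at 10% *of the output range*
(an absolute 0.1 for the sigmoid-bounded generator). Thresholding against
each image's own maximum was rejected: an all-noise prediction would then
always produce a mask, where the absolute rule correctly yields an empty
one. `largest_component()` labels 8-connected components and keeps the
largest; equal sizes are broken in favour of the component containing the
smallest row-major pixel index (deterministic and testable). Centroids are
arithmetic means of member-pixel coordinates. `track_arc()` assembles
per-frame records - centroid errors split into AP/LAT (detector u) and SI
(detector v), converted to isocentre mm, plus Dice and mean surface
distance - and flags frames with empty predictions rather than imputing
them; flagged frames are excluded from summaries and counted.

## Ground-truth construction utilities

Two test-set modes mirror the two clinical ground-truth pathways:

* **Masked mode** (`make_masked_testset()`): markers are embedded in the
  volume, kV-like images projected, marker footprints removed by harmonic
  inpainting - each masked pixel satisfies the discrete Laplace equation
  with Dirichlet boundary from the surrounding pixels, solved directly as a
  sparse SPD system (residual < 1e-6 of the image maximum; no iterative
  fallback is needed at these sizes) - and Poisson noise applied
  afterwards. The photon budget parameterisation (`photons_at_max`,
  default 1e4) controls noise amplitude, which the source setting leaves
  unspecified. With the phantom, marker footprints come from projecting the
  known marker spheres (dilated by one pixel); no image-based marker
  detection is needed or included.
* **Markerless mode** (`make_markerless_testset()`): clean projections are
  shifted in the detector frame by the projective image of a known 3D couch
  shift, and ground-truth masks are shifted identically - the ground truth
  is an *average* position, as in soft-tissue-registration-based practice.

Inpainting obeys the discrete maximum principle and restores harmonic
(constant/affine) fields exactly; both properties are tested, in 2D and in
the 6-neighbour 3D analogue (`mask_markers_3d()`).

## Evaluation

`dice()`, `mean_surface_distance()` (symmetrised mean nearest-boundary
distance, 4-neighbour boundary definition, Euclidean distances in isocentre
mm), `summarize_tracking()` (mean, sample SD, MAD, 5th/95th percentiles),
`pearson()` (via `stats::cor`), `bland_altman()` (differences error −
motion against pairwise averages; limits at ±1.96 SD) and
`per_angle_stats()` (per-bin mean and percentiles, empty bins reported)
follow the conventions of the tracking-accuracy literature. Two decisions
deserve a note: **MAD** here is the *mean absolute deviation of the error
about zero*, `mean(|error|)` - consistent with how reported MAD values sit
between |mean| and SD in this literature; a median-based MAD was rejected.
Percentiles use linear interpolation between order statistics (R type 7).
All metric implementations are cross-checked against brute-force
enumerations on random masks.

## Problem sizes and determinism

The package's default configurations are desk-scale: 32³-48³ voxel
phantoms, 64×64 detectors, 8-angle arcs, 8 augmentations, 10 epochs - a
full pipeline runs in a few minutes on one CPU core, and the test suite's
paper-scale cardinality check (360-image arc, 36,000 streamed pairs) in a
few more. Full-scale settings (512×512, 1° steps, 100 augmentations, 20
epochs) are reachable through the same interfaces but are GPU-scale work.
Every stochastic stage (phantom texture, transform sampling, network
initialisation, batch shuffling, Poisson noise) consumes R's RNG under an
explicit seed; reruns are bit-identical under equal seeds and thread
counts.

## Known limitations

* The phantom's elevated prostate contrast (above) is the big one: results
  here validate mechanics, not clinical accuracy.
* 2D only: position in the imager plane at each angle. Inferring 3D
  coordinates from the rotating 2D frames is explicitly out of scope.
* The projector ignores scatter, beam hardening, detector response and
  polychromatic spectra.
* The rigid-transform inverse-composition test is exact only for pure
  translations; a composed Euler-triple inverse is not representable as a
  single x→y→z triple in general.
* Bland-Altman "observed motion" is defined as the ground-truth centroid
  displacement from the arc's reference position per direction; other
  pairings are possible and the functions accept any two series.
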