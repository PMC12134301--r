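# kvtrack

Patient-specific markerless prostate tracking in kilovoltage (kV) projection
images, end to end in R.

During arc radiotherapy the prostate moves while the gantry rotates around
the patient. The on-board kV imager provides a 2D projection at every gantry
angle, but prostate soft tissue is nearly invisible in x-ray images, so
clinics implant gold fiducial markers as position surrogates — with the
costs, delays and risks of an implantation procedure. A markerless
alternative trains an image-to-image network *per patient*, before
treatment, from data that already exists: the planning volume and the
physician's prostate contour are forward-projected into paired synthetic
images over the full 360° arc (digitally reconstructed radiographs paired
with prostate-mask projections), a conditional GAN learns the mapping, and
at treatment time the generator segments each incoming kV frame.

The conditional GAN is a UNet generator `G` against a PatchGAN
discriminator `D`, trained to minimise

    G* = arg min_G max_D  L_cGAN(G, D) + λ · L_L1(G),        λ = 100
    L_cGAN = E[log D(x, y)] + E[log(1 − D(x, G(x)))]
    L_L1   = E‖y − G(x)‖₁

where `x` is the kV-like input and `y` the mask projection. Predictions are
binarised at 10% of the output range, the largest 8-connected component is
kept, and its centroid — converted to millimetres at the isocentre plane via
the pixel pitch and the SAD/SID magnification (0.26 mm per pixel at the
standard 0.39 mm pitch and 1.5 magnification) — is the tracked position.
A 3D couch shift maps into the rotating detector frame as

    (u, v) = SID / (SAD − (x·cosθ + z·sinθ)) · (x·sinθ − z·cosθ, y)

so along-beam motion is invisible and in-plane motion is magnified by
SID/SAD.

Everything runs against a synthetic digital-pelvis phantom (ellipsoidal
body, bones, prostate, optional fiducial markers) with analytically known
geometry, so each stage is verifiable offline: the ray-cast projector
against a dense independent integrator, harmonic (Laplace/Dirichlet) marker
inpainting against exact restorations, metrics against brute-force
enumeration, and the whole loop against geometry closed forms. The
neural-network engine (im2col/GEMM convolutions with hand-derived backprop
and Adam) is implemented in RcppArmadillo and gradient-checked against
finite differences.

## Worked example

A desk-scale end-to-end run — phantom, 64 paired projections, 10 training
epochs, tracking on 8 held-out gantry angles — takes a couple of minutes on
one CPU core:

```r
library(kvtrack)
res <- run_pipeline(run_config(seed = 1))
print(res$summary)
```

```
<metrics_summary> n = 8 (0 dropped)
  AP/LAT error: 0.44 +/- 1.38 mm (MAD 1.20; p5 -0.96, p95 2.14)
  SI error:     -0.38 +/- 0.19 mm (MAD 0.38; p5 -0.58, p95 -0.12)
  DSC: 0.839 +/- 0.020 (p5 0.818, p95 0.868)
  MSD: 3.15 +/- 0.39 mm (p5 2.57, p95 3.55)
```

Reading this: on the eight gantry angles the model never saw, the tracked
centroid lands within ~1.2 mm (mean absolute deviation) of the true
prostate-mask centroid in the AP/LAT direction and ~0.4 mm in SI, with a
mean Dice overlap of 0.84 between predicted and true masks and no dropped
(empty-prediction) frames. The phantom's prostate is deliberately given
elevated radiographic contrast so that this scaled-down check trains in
minutes — the numbers validate the pipeline's mechanics, not clinical
accuracy (see the vignette for exactly what they do and do not show).

Individual stages are ordinary functions: `generate_phantom()`,
`forward_project()` / `generate_arc()`, `build_training_set()`,
`train_patient_model()`, `segment()` / `track_arc()`,
`summarize_tracking()` / `per_angle_stats()`, plus the ground-truth
utilities `make_masked_testset()` (marker embedding → harmonic inpainting →
Poisson noise) and `make_markerless_testset()` (known couch shift applied
through the projective mapping). A thin CLI wrapper lives at
`inst/cli/kvtrack.R` (`kvtrack {phantom|project|run}`). Volumes are NIfTI;
records and tables CSV; summaries JSON.

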