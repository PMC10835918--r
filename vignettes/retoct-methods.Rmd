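---
title: "Methods: models, parameters and design choices in retoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in retoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models each
stage implements, the assumptions behind them, the tunable parameters and
why their defaults are what they are, what the synthetic phantom does and
does not emulate, and the choices we made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Longitudinal small-animal OCT studies ask how individual retinal layers
change after an insult — here the motivating setting is unilateral
excitotoxic injury with the untouched contralateral eye as an internal
control, imaged at baseline and days 3, 7 and 28. The measurement chain is
long (motion correction, segmentation of ten thin layers, surface-based
thickness, regional averaging, paired statistics), and each stage can bias
the layer trajectories. The package therefore treats a fully synthetic,
ground-truth-complete phantom cohort as a first-class citizen: every stage
is validated by recovery of known injected quantities.

## The phantom: a stated world

`phantom_config()` describes a curved ten-layer retina on the native
acquisition grid (400 × 400 × 1024 voxels over 1.6 × 1.6 × 1.64 mm, i.e.
4 µm lateral and ~1.6 µm axial voxels). The components:

- **Geometry.** Boundary k is a quadratic dome plus the cumulative sum of
  layer thicknesses. Baseline thicknesses (µm): ILM-RNFL 12, GCL 15,
  IPL 45, INL 30, OPL 15, ONL 55, ELM 5, PRL 30, RPE 12, BM 4 (total
  223 µm), choroid 60 below BM. These are chosen once as realistic adult
  rat values; no baseline table is prescribed by the motivating study.
  Dome coefficient 4e-5 /µm (≈50 µm sag at the lateral corners) — a mild,
  realistic curvature that also fits the desk-scale axial field of view.
- **ONH pit.** Inside `onh_radius_um` (150 µm) all layer thicknesses are
  scaled by `min(1, (r/r_onh)²)`, so the boundaries converge at the pit
  centre. The pit's precise shape is cosmetic: analysis always masks the
  ONH with a wider margin, so only the existence and location of the
  convergence region matter (they drive `detect_onh_center()`).
- **Speckle.** Fully developed multiplicative speckle is approximated by
  unit-mean gamma noise with shape k (`speckle_shape`, default 16, i.e.
  25% intensity SD). The device's true noise statistics are unknown; k is
  deliberately a free parameter and `Inf` gives the noiseless limit used
  by exactness tests.
- **Vessel shadows.** Discs at the RNFL level attenuate everything beneath
  them (default factor 0.45), emulating projection artifacts.
- **Motion.** Per-B-scan axial displacement as a random walk (default step
  SD 2 px), applied by linear interpolation (integer shifts exact, which
  gives the exact-inverse test its teeth).
- **Cohorts.** For subject s, eye e, day d, layer l the effective
  thickness is `base_l · subj_{s,l} · m_{l}(e,d) · visit_{s,e,d,l}` with
  `subj` lognormal (σ = 0.03, stable per subject — shared by both eyes and
  all days) and `visit` lognormal (σ = 0.01, independent per visit). The
  stable component cancels in the paired design; the visit component is
  what the paired t-test sees. σ values are chosen once so that n = 9
  paired tests have high power against the injected effects while day-0
  comparisons stay null; the motivating study publishes no between-animal
  variance to copy.

**The packaged effect profile.** `paper_effects()` encodes the injured
eye's per-layer multipliers at days 3/7/28. The published quantities are
composite: inner retina (ILM→ONL) −10.5% at day 7 and −15.8% at day 28,
outer retina (ELM→BM) −3.9% at day 7 and +5.5% at day 28, plus a
qualitative per-layer narrative (IPL thinning from day 3, INL from day 7,
ILM-RNFL thickening at day 3 then thinning at day 28, early ELM/RPE/BM
thinning with later ELM/RPE normalization, late PRL thickening). The
per-layer multipliers follow that narrative and were calibrated *once*,
analytically against the baseline thicknesses (thickness-weighted sums),
to reproduce the printed composite values; they are fixed constants, not
fitting targets.

What the phantom does **not** emulate: optical physics (no interferometric
A-scan model, dispersion, depth-dependent attenuation or sensitivity
roll-off), lateral eye motion, blink/saccade artifacts, intensity
inhomogeneity across the field, pathology-induced texture change (only
thickness changes), or anatomically realistic ONH structure. A green
end-to-end test therefore establishes that the *measurement chain* is
unbiased and powerful under the stated noise model — not that segmentation
of real injured tissue is solved.

## Motion correction

Pairwise offsets maximize the normalized cross-correlation of adjacent
B-scans over integer shifts (±`max_shift_px`), with parabolic subpixel
refinement, evaluated on the central 50% axial band so background speckle
does not dominate. Offsets are accumulated into a cumulative profile and a
least-squares polynomial (default order 2) is fitted; only the residual is
corrected. Rationale for detrending the *cumulative* profile: the retinal
dome and scan angle appear exactly as a smooth trend of the cumulative
profile, and a polynomial of the dome's order removes them from the
correction, preserving anatomy. Consequences worth knowing:

- The estimated raw profile on a motion-free curved phantom is *not* zero —
  it is the dome trend. Recovery tests must compare detrended profiles.
- Any smooth (polynomial) component of true motion is indistinguishable
  from anatomy and is deliberately preserved; only jitter is corrected.
- A constant B-scan has undefined correlation; the pair gets offset 0 with
  a warning.

## Bounded-variation denoising

`bv_smooth()` minimizes `||u − f||² + w·TV(u)` with anisotropic TV (L1 of
forward differences along the three axes) by Chambolle-style dual
projection (step τ = 1/12, the 3D stability bound; componentwise clamping
of the dual field matches the anisotropic functional; stopping at relative
max-change `tol` or `max_iter`). Because the minimizer satisfies
`w·TV(u*) ≤ w·TV(f)`, the TV-nonincrease test is a direct check of solver
correctness. The denoised volume is for visualization and manual labeling
only — training and inference run on raw intensities, and both
`predict_volume()` and the pipeline log enforce/record that routing. SNR
is monotone in `w` only on the rising part of the curve; at large `w`,
smoothing ramps across region boundaries can raise the background SD
again, which is why the monotonicity test uses a small-weight grid.

## Segmentation at reduced scale

No deep-learning framework is available in the supported dependency set,
so the full encoder–decoder described for this problem class is reduced to
an architecture trainable in seconds on one CPU: a *fixed* multiscale
convolutional feature extractor (raw and box-smoothed intensities at three
scales, axial gradient and its magnitude, normalized depth, and depth
relative to the brightest smoothed band of the A-scan) feeding a trainable
two-hidden-layer dense network whose last layer is the pixel-wise
classification head. The transfer-learning protocol is preserved exactly:

1. pretrain on a *source-domain* phantom (different reflectivities and
   thicknesses) as a stand-in for external pretrained weights we cannot
   ship;
2. **frozen stage** — all tensors except the head are frozen bit-exactly,
   only the head adapts (the freeze is asserted by tensor identity in
   tests);
3. **finetune stage** — everything unfreezes, affine augmentation active
   (translations uniform up to 20 px per axis with random sign, rotation
   up to 30° with random sign, zoom 0.75–1.25, lateral flip p = 0.5, never
   an axial flip; image bilinear, labels nearest-neighbor);
4. **pseudo-label round** — the model segments unlabeled baseline volumes,
   predictions join the manual labels with equal weight, and a second
   finetune round runs at half the learning rate (resuming from a
   converged model; the halving is our choice, no optimizer details are
   prescribed).

Every stage returns the best-validation-loss checkpoint, with the initial
state included as epoch 0 — so a training round that does not help cannot
hurt, which is also what makes the pseudo-label "no degradation" contract
hold structurally. Training samples pixels stratified per class (thin
layers like ELM and BM would otherwise be overwhelmed), and all RNG flows
from a single config seed, making training bit-reproducible in
single-threaded BLAS conditions. An optional cascade stage retrains a
second network on features augmented with the first stage's smoothed class
probabilities (an auto-context reduction of the anatomical cascade idea);
it is off by default.

Label post-processing (topological ordering) is deliberately *not* baked
into the network: the surfaces module enforces it, so the contract holds
for any label source.

## Surfaces and thickness

Boundary k is the per-A-scan depth of the first voxel of layer k
(boundary 11: first choroid voxel). Convention: boundaries sit on voxel
top faces; with voxel centres at k − 0.5 this makes phantom recovery
unbiased to half a voxel. A-scans missing a class (ONH, segmentation
failures) are filled by an iterated 5×5 median inpaint and flagged invalid
for ROI statistics; ordering violations are projected onto the monotone
cone by pool-adjacent-violators per A-scan (applied only where violations
exist — ground-truth labels never trigger it).

Height maps are bilinearly resampled to an isotropic lateral grid (1.6 µm
at native 4 µm spacing, i.e. 1000 × 1000 samples; desk-scale runs use
8–16 µm to stay within CPU budgets — a resolution, not a method, change).
Thickness is the k = 1 nearest-neighbor Euclidean distance from each
upper-boundary point to the lower boundary in 3D µm space (the
cortical-thickness-style shortest distance). The default is the directed
upper→lower distance; a symmetric variant (mean of both directions) is a
flag, as directionality is not prescribed. The search is restricted to a
lateral window (default ±25 µm): at retinal slopes (a few degrees) the
true nearest point lies well inside it, and tests verify exact agreement
with a brute-force all-pairs search. One practical caveat encoded in the
ROI defaults: near the ONH pit the converging boundaries attract
nearest-neighbor searches from outside the pit, so the exclusion disc must
be at least pit radius + window ("wide margin").

Composites (inner ILM→ONL, outer ELM→BM, total ILM→BM) use the span
between the outermost bounding surfaces, not the sum of per-layer maps;
the sum variant exists for cross-checks (they agree to <1% on curved
geometry, exactly on flat).

## ROI and statistics

Full / central / peripheral are annuli around the ONH centre with radii
(r_onh, r_mid, r_outer) = (160, 460, 760) µm by default: no radii are
published for the motivating study, so these are configuration, not
constants — 160 µm is a wide margin around the 150 µm pit, 760 µm is the
largest disc comfortably inside the 1.6 mm field, 460 µm the midpoint.
Membership is by pixel centre; full is exactly central ∪ peripheral, so
area-weighted means satisfy the partition identity to machine precision.

Statistics follow the stated recipe: two-sided paired t-test per
(measure, region, day) on injected−control differences (closed form,
n−1 df), Benjamini–Hochberg step-up FDR at q = 0.1, significance at
corrected p < 0.05. The q = 0.1 level and the p < 0.05 threshold on
*adjusted* values are both reproduced as stated, not reconciled. The
correction family defaults to one measure × region panel (the unit at
which corrected p-values are displayed together); a global family is a
flag. Zero-variance differences yield a flagged record with undefined p
(identical samples: t = 0, p = 1).

## Numerical choices and degenerate inputs

- Shift search range must leave the central registration band inside the
  volume; violations error early.
- Subvoxel B-scan shifts use linear interpolation; integer shifts take an
  exact copy path so the inverse test is bitwise outside fill margins.
  Fill values resample the B-scan's top (vitreous) margin.
- `tv_denoise` output is clipped to the input range (the continuous
  minimizer satisfies a maximum principle; clipping guards the discrete
  iterate at early stopping).
- Bilinear resampling extrapolates linearly in the half-pixel rim outside
  input pixel centres; tests exclude that rim where exactness is claimed.
- Ties in argmax-based label prediction resolve to the first (lowest)
  class index deterministically.
- All cohort/test RNG is seeded; derived child seeds stay below 2³¹.

## Desk scale and budgets

Cohort-level tests and the acceptance script run a desk-scale phantom
(64 × 64 × 288 voxels, same lateral FOV, same 1.6 µm axial pitch) with
8–16 µm isotropic resampling targets. This keeps the full 9-subject,
72-volume end-to-end run at ~1.5 min and the whole suite within CI
budgets. Exactness-sensitive checks (brute-force thickness oracle, 1.6 µm
parameter recovery) run at native spacing on reduced lateral extents
instead. Scaling down changes sampling density, not the algorithms.

## Known limitations

- The segmentation model is a per-pixel classifier over engineered
  features; it matches the protocol and contracts of the full cascaded
  network but not its capacity. On real, pathological, texture-shifted
  data its accuracy would not transfer; the package's claims are about the
  pipeline around it.
- Only axial motion is modeled and corrected; lateral motion is out of
  scope.
- Height-map surfaces cannot represent folds or the true ONH topology;
  the ONH is masked rather than modeled.
- The NIfTI-1 reader parses only the fields this package writes; it is an
  interchange format here, not a general-purpose medical-image reader.
- Repeated-measures/mixed models are out of scope; the analysis is
  per-day paired testing as stated.
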