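---
title: "Attenuation correction for small-animal PET: models, parameters and design choices"
author: "petac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation correction for small-animal PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petac)
```

## The physical model

A 511 keV annihilation photon traversing matter survives with probability
$\exp(-\int_L \mu\,dl)$, where $\mu(x,y)$ is the linear attenuation
coefficient map (cm$^{-1}$) and $L$ the photon's path. A PET coincidence
requires *both* photons to escape, and because the two paths together span
the full chord of the object along the line of response (LOR), the joint
survival probability depends only on the total intersection length:

$$P(s,\varphi) = e^{-\int_{L(s,\varphi)} \mu(x,y)\,dl},$$

with $\varphi$ the projection angle and $s$ the radial position. The
measured projections are therefore the attenuated Radon transform of the
activity $f$:

$$p(s,\varphi) = \int_{L(s,\varphi)} f(x,y)\,
  e^{-\int_{L(s,\varphi)}\mu\,dl}\,dr .$$

Because the exponential factor is constant along each LOR, it factors out
of the activity integral. `attenuated_forward()` exploits this exactly: it
computes the unattenuated projection and divides by the
attenuation-correction-factor (ACF) sinogram
$\mathrm{ACF}(s,\varphi) = \exp(+\int \mu\,dl) \ge 1$ from
`acf_sinogram()`. The identity
`attenuated_forward x ACF == radon_forward` holds to machine precision and
is asserted by the test suite; it is also what makes sinogram
*precorrection* (multiplying measured counts by the ACF) an exact inverse
of attenuation in the noiseless limit.

At mouse and rat scales the effect is far from negligible: a 50 mm water
cylinder attenuates the central LOR by $e^{-0.0969 \times 5} \approx 0.62$,
and the uncorrected reconstruction of a uniform cylinder shows the classic
cupping artifact.

## The two correction routes

**CT route** (`run_ct_ac()`): a CT volume is converted to $\mu$ at 511 keV
through a quadratic calibration $\mu = a_1\,\mathrm{HU}^2 +
a_2\,\mathrm{HU} + a_3$ fitted by unweighted least squares on insert
measurements (`fit_calibration()`); the CT frame is rigidly aligned to the
PET frame using fiducial beads (`detect_fiducials()`,
`estimate_rigid()`, `resample()`); the resulting $\mu$-map yields an ACF
sinogram; measured counts are precorrected and reconstructed with OSEM.

**Segmentation route** (`run_se_ac()`): the uncorrected emission
reconstruction is thresholded into air versus body
(`segment_emission()`), the largest connected component is kept, internal
holes are filled slice-wise, and the mask is assigned the uniform water
coefficient 0.0969 cm$^{-1}$ (`mask_to_mumap()`). No CT, no registration,
no extra dose.

Both routes are scored by the recovery values

$$RV_{CT} = \frac{ROI_{AC\text{-}CT}-ROI_{NC}}{ROI_{AC\text{-}CT}},\qquad
  RV_{SE} = \frac{ROI_{AC\text{-}SE}-ROI_{NC}}{ROI_{AC\text{-}CT}},$$

both normalized by the CT-corrected ROI mean — implemented exactly in that
form in `recovery_values()` (the shared denominator makes the two numbers
directly comparable; the package regression-tests this arithmetic against
the full set of published ROI means in `reported_study_means()`) — and by
the profile flatness $F = (C_{max}-C_{min})/C_{min}$ of a uniform
phantom's interior profile.

## Tunable parameters

* **Projector geometry** — 120 angles over $[0,\pi)$, 175 radial bins of
  0.5 mm (`sinogram_geometry()`). The odd bin count puts the central bin
  through the isocenter; 0.5 mm bins are at the Nyquist rate for the 0.5 mm
  reconstruction voxels. The FOV (87.5 mm) must contain the object:
  truncation is an error, not a warning.
* **OSEM** — 8 interleaved angular subsets, 10 iterations, uniform unit
  initialization (`recon_config()`). The studies the package models do not
  state their reconstruction settings, so these are the package's own,
  chosen for stable convergence of 140-pixel water cylinders; they are
  recorded in every report's provenance. With one subset the algorithm is
  exactly MLEM (tested bitwise against an independent implementation).
* **Calibration** — `default_calibration()` carries the published scanner
  coefficients $a_1 = -2.05\times10^{-8}$, $a_2 = 9.66\times10^{-5}$,
  $a_3 = 0.12$ cm$^{-1}$ ($r^2 = 0.993$). Note $\mu(0) = 0.12 \ne
  \mu_{water}$: this scanner's CT-number scale is not anchored at
  water = 0. The package therefore never assumes a standard Hounsfield
  anchor; synthetic CTs are always generated by inverting the *active*
  curve, which keeps the round trip exact by construction.
* **Segmentation threshold** — the studies never state their global
  threshold. Default policy: 10% of the 99th-percentile intensity.
  Anchoring on a high percentile rather than the maximum keeps hot spots
  (tumour, bladder, fiducials) from dragging the threshold up; a relative
  threshold makes the mask invariant to global intensity scaling. An exact
  Otsu policy (exhaustive maximization of between-class variance) is
  available as `segment_policy("otsu")`.
* **Flatness interior window** — 70% of the object's support along the
  profile. An edge-inclusive minimum would be dominated by partial-volume
  roll-off at the cylinder boundary and could never produce the published
  1–3% corrected flatness values; the fraction is a `flatness()` argument
  and is logged with every report.
* **Evaluation ROI** — a central disk of half the phantom radius on the
  central slice; for hot-sphere phantoms, a sphere of 80% of the insert
  radius (pulled in to reduce partial-volume contamination at the insert
  boundary).

## What the synthetic data emulates — and what it does not

The phantom factory reproduces the three phantom studies: a 30 mm
mouse-sized cylinder (~1 MBq/cc), a 50 mm rat-sized cylinder (~0.5 MBq/cc),
and the rat cylinder with a hot sphere at 4:1 sphere-to-background ratio —
all water-filled, with optional high-activity fiducial beads around the
body. Defaults that the source studies leave open, fixed once here:
0.5 mm in-plane voxels (90/140 pixels for mouse/rat), five 2 mm slices
standing in for the short axial FOV (seven for the hot-sphere phantom, so
the 6 mm sphere fits axially), hot sphere of 6 mm radius centred 10 mm
off-axis, fiducial beads of 2 mm radius 5 mm off the surface at 5/4/3
MBq/cc. Acquisition noise is Poisson with ~2 × 10⁶ expected coincidences
per study, a desk-scale stand-in for a 20-minute scan.

The simulator is deliberately idealized. It omits, on purpose:

* fully-3D acquisition and Fourier rebinning — everything is per-slice 2D,
  a known cause of mild differences from physical scanner numbers;
* randoms, scatter, detector blur, dead time and decay (the modelled
  studies also applied no randoms/scatter corrections);
* polyenergetic CT physics: synthetic CTs are generated directly in CT
  numbers by inverting the calibration, so beam hardening cannot arise;
* anatomically realistic rodents; the phantom wall is not modelled by
  default (wall thickness is unstated in the source studies) but a shell
  of acrylic ($\mu = 0.1120$) is expressible as a second material.

Passing tests therefore demonstrate the correctness of the correction
*algorithms* under ideal physics, not the absolute accuracy of any scanner.
Absolute ROI values in counts/s are not reproducible at a desk (they
depend on scanner sensitivity and reconstruction settings that are not
public); only ratios — recovery values, flatness — are meaningful
comparisons, and those are what the package reports.

## Numerical choices

* **Line integration** is Joseph's interpolating ray-driven method,
  assembled once per (geometry, grid) into a sparse system matrix. The
  matrix transpose is then the *exact* adjoint, which ordered-subsets EM
  requires; the adjoint identity is tested to 10⁻¹⁰.
* **Units**: $\mu$ is stored in cm$^{-1}$, all geometry in mm; path
  lengths are converted by /10 exactly once, at the exponent, so no
  double-scaling bug is possible.
* **Rasterization** is area-weighted: boundary voxels receive the coverage
  fraction of the analytic solid, estimated by regular 5×5(×3) subvoxel
  sampling. This removes the staircase bias a binary mask would leave in
  line integrals; the disk area converges to $\pi R^2$ (tested at two
  resolutions) and is accurate to well under 0.5% at the default grids.
* **Reconstruction support** is restricted to the inscribed radial FOV
  circle: voxels beyond it are seen by an incomplete set of angles and
  cannot be estimated consistently, so they are masked out of the OSEM
  update (as is any voxel with zero sensitivity) rather than risking
  division blow-ups.
* **Degenerate inputs** fail loudly and early: truncated objects,
  negative $\mu$, non-ACF sinograms passed to `precorrect()`, identically
  zero emission images, collinear or reflected fiducial configurations,
  $\mu$ values outside the calibration's attainable range.
* **Subset order** is interleaved and fixed; all randomness (Poisson
  counts, CT noise) flows from explicit seeds; every run is bit-for-bit
  reproducible.

## Design choices where the source was open

* **Correction is applied by sinogram precorrection** (counts × ACF before
  OSEM), mirroring the modelled workflow. A `system-matrix` mode, which
  folds 1/ACF into the forward model, is retained as a cross-check; both
  agree on noiseless data. Precorrected data are no longer Poisson, which
  is acceptable here because the evaluation criteria are ratio-based.
* **Fiducial correspondence is by intensity rank.** The original
  registration was manual (correspondence implicit in the operator's
  clicks); the simplest deterministic surrogate is to give the synthetic
  beads distinct activity and density levels in matching rank order and
  sort detections by mean intensity.
* **Body exclusion in blob detection is guarded.** The body is "the
  largest component", but when the threshold already removed the body, the
  largest component is a bead; the body is therefore only excluded when it
  is at least 4× the runner-up's size. A bead and a body differ in volume
  by orders of magnitude, so the guard is safe on both sides.
* **Flat extrapolation outside the calibrated HU range.** The fitted
  parabola turns over near HU ≈ 2.4 × 10³, which would map very dense
  material to *falling* $\mu$; clamping to the domain edge is the
  conservative choice.
* **Bone is mapped to soft tissue** in the segmentation route — no bone
  class is added. This is the method's documented failure mode for
  bone-seeking tracers (the spinal-column study shows the largest CT/SE
  disagreement), and modelling it away would misrepresent the method.
* **The Monte Carlo validation arm is replaced by an analytic
  attenuation-free reference** (`run_attenuation_comparison()`): the claim
  being validated is that the corrected image behaves like one simulated
  without attenuation, and the analytic projector tests exactly that
  contract at desk scale. Beam-hardening physics is out of scope with it.
* **Single-route reports**: `run_se_ac()` alone cannot form the published
  $RV_{SE}$ (whose denominator is the CT-corrected mean), so its report
  normalizes by the SE-corrected mean instead; `run_phantom_study()` runs
  both routes on the same counts and reports the published form.

## Problem sizes and what the package computes

The shipped experiments run at the default grids above: the noiseless 2D
rat study (140² pixels, 120×175 sinogram) reconstructs in seconds and
yields uncorrected interior flatness near 20% against the published 22–23%
(a 2D analytic surrogate for a physical 3D scan, expected to sit slightly
low), corrected flatness under 2%, and a count increment of ~44% versus
the attenuation-free reference. The noisy five-slice studies at 2 × 10⁶
counts give $|RV_{CT}-RV_{SE}|$ of a few tenths of a percentage point on
uniform phantoms — comfortably inside the published 2–3 pp agreement — with
rat $RV_{CT}$ around 46% and mouse around 31%. None of these numbers is
stored: the test suite and `scripts/acceptance.R` recompute all of them.

## Known limitations

2D-only geometry; no scatter/randoms/partial-volume modelling; no
resolution modelling or regularization in OSEM; rank-based fiducial
matching assumes distinguishable bead intensities; the segmentation route
assumes the tracer delineates the body outline (it fails gracefully — with
a diagnostic — when the emission image is empty, but a tracer with very
focal uptake will under-segment the body, and bone is always assigned the
water coefficient).
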