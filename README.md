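# petac — attenuation correction for small-animal PET

Photon attenuation makes uncorrected PET underestimate radiotracer
concentration, most severely at the centre of the object (the *cupping*
artifact). The effect is well known in clinical imaging but is substantial
even at preclinical scale: a 50 mm water cylinder attenuates its central
line of response by a factor e^(−0.0969 cm⁻¹ × 5 cm) ≈ 0.62. `petac` is
for physicists and methodologists working on preclinical PET
quantification: it implements, simulates and evaluates the two standard
correction routes end to end, without needing a scanner.

The measured projections follow the attenuated Radon transform

    p(s, φ) = ∫_L(s,φ) f(x, y) · exp(−∫_L(s,φ) μ(x, y) dl) dr

where `f` is the activity image and `μ` the attenuation map at 511 keV. In
PET the exponential factor depends on the whole chord, so attenuation is
undone exactly in the sinogram domain by multiplying each LOR by its
attenuation correction factor `ACF = exp(+∫ μ dl)`. The package provides:

* **CT-based correction (CT-AC)** — quadratic CT-number calibration
  `μ = a₁·HU² + a₂·HU + a₃`, fiducial-based rigid coregistration of the CT
  to the PET frame, ACF precorrection, OSEM reconstruction;
* **segmented-emission correction (SE-AC)** — global-threshold
  segmentation of the uncorrected emission image into a body mask,
  uniform water μ (0.0969 cm⁻¹), ACF precorrection, OSEM — no CT, no
  registration, no extra dose;
* an **analytic phantom factory** (mouse/rat cylinders, hot-sphere insert,
  fiducial beads), an attenuated-Radon **projector** with Poisson count
  sampling, **2D OSEM**, and the evaluation statistics: recovery values

      RV_CT = (ROI_AC-CT − ROI_NC) / ROI_AC-CT
      RV_SE = (ROI_AC-SE − ROI_NC) / ROI_AC-CT

  (note the shared CT-corrected denominator) and profile flatness
  `F = (Cmax − Cmin)/Cmin`.

See the methods vignette (`vignettes/attenuation-correction.Rmd`) for the
model, parameter defaults and design rationale.

## Worked example

Recovery-value arithmetic on the reported uniform rat-phantom ROI means:

```r
library(petac)
recovery_values(roi_nc = 210.34, roi_ac_ct = 405.32, roi_ac_se = 396.17)
#> $rv_ct
#> [1] 48.10520
#> $rv_se
#> [1] 45.84773
```

i.e. attenuation correction recovers 48.1% (CT route) and 45.8% (SE route)
of the corrected counts in a 50 mm water phantom.

Simulate that phantom and quantify the cupping artifact (noiseless 2D
study, default 120-angle × 175-bin projector and 8-subset × 10-iteration
OSEM):

```r
cmp <- run_attenuation_comparison(rat_phantom(n_slices = 1))
cmp[c("flatness_uncorrected", "flatness_corrected", "count_increment_percent")]
#> $flatness_uncorrected
#> [1] 19.69770
#> $flatness_corrected
#> [1] 1.742668
#> $count_increment_percent
#> [1] 43.68323
```

The uncorrected reconstruction cups by ~20% across the interior of the
cylinder; after correction with the true μ-map the profile is flat to
better than 2%, and the attenuation-free reference shows the correction recovers a
~44% count deficit.

Run both full pipelines — Poisson counts, synthetic CT on a rigidly offset
grid, fiducial registration, calibration, segmentation — on the same data:

```r
rep <- run_phantom_study(rat_phantom(), total_counts = 2e6, seed = 1)
c(rv_ct = rep$rv_ct, rv_se = rep$rv_se)
#>    rv_ct    rv_se
#> 45.98685 45.80989
```

The two correction routes agree to a fraction of a percentage point on a
uniform water phantom, which is the package's central reproduction of the
phantom experiments it models.

A thin command-line front end over these functions is installed at
`inst/cli/petac` (subcommands `simulate`, `calibrate`, `mumap-ct`,
`mumap-se`, `correct`, `recon`, `evaluate`, `run-ct-ac`, `run-se-ac`,
`compare-attenuation`; every run writes a JSON manifest of all parameters
used).

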