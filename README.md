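# pinspect

Simulation and reconstruction toolbox for **single-pinhole SPECT of small
laboratory animals on an adapted clinical gamma camera**, with
phantom-based spatial-resolution characterization.

Clinical gamma cameras (large NaI(Tl) detectors, ~4 mm intrinsic
resolution) can image millimetre-scale rodent organs when a pinhole
collimator projects a magnified, inverted image of a target rotated in
front of the detector. `pinspect` models that acquisition chain —
pinhole geometry with edge-penetration, finite-aperture cone projection,
detector blur, Poisson counting — and reconstructs the activity
distribution with MLEM/OSEM, so the resolving power of a configuration
can be established with digital hot-rod and capillary phantoms before any
hardware is built.

## The model

* Magnification `M = f / b` (pinhole–detector over pinhole–target
  distance).
* Penetration-corrected aperture
  `d_eff = sqrt(d (d + (2/mu) tan(alpha/2)))` for a double-cone pinhole
  of bore `d`, material attenuation `mu`, opening angle `alpha`.
* Predicted system resolution (FWHM at the target plane)
  `R = sqrt((R_int/M)^2 + (d_eff (M+1)/M)^2)`.
* Forward operator: voxel-driven splatting through sampled aperture
  points with solid-angle weights, followed by the detector's intrinsic
  Gaussian; `back_project()` is its exact adjoint (verified against a
  dense-matrix oracle in the tests).
* Reconstruction: OSEM — multiplicative Poisson EM over angle-interleaved
  subsets, count-matched uniform start, optional Gaussian inter-iteration
  smoothing (FWHM in voxels), fixed iteration count.
* Scoring: line profiles across rows of phantom features; a feature size
  counts as resolved when the mean valley/peak contrast falls below a
  Rayleigh-like criterion (0.735 by default).

## Worked example

Inspect a configuration analytically:

```r
library(pinspect)
m <- system_model(detector_spec(224, 224, pixel_pitch = 1.75),
                  collimator_spec(1.5, "lead"),
                  acquisition_geometry(36, 252, n_projections = 40))
print(m)
#> Pinhole SPECT system model
#>   detector: 224 x 224 mm, pitch 1.75 mm (128 x 128 px), intrinsic FWHM 3.90 mm
#>   collimator: lead, bore 1.50 mm, mu 2.70 /mm, d_eff 1.700 mm
#>   geometry: b 36.0 mm, f 252.0 mm (M = 7.00x), 40 projections
#>   predicted resolution 2.022 mm FWHM; max target 32.0 mm; 7 aperture samples
```

The 1.5 mm lead pinhole at 7x magnification acts like a 1.70 mm hole once
edge penetration is counted, supports targets up to 32 mm across, and has
a single-view resolution of about 2 mm.

Run the full rat-configuration resolution study (hot-rod phantom with
0.5/1.0/1.5/2.0 mm sectors, 40 noisy projections at ~1e5 counts each,
OSEM with 20 iterations / 4 subsets / 1.5-voxel smoothing every 2):

```r
study <- run_resolution_study("rat", seeds = c(101L, 102L, 103L))
print(study)
#> resolution_study 'rat', 3 seeds, unanimous
#> resolution_report (criterion 0.735 )
#>   0.50 mm: contrast 0.986 -> not resolved
#>   1.00 mm: contrast 0.879 -> not resolved
#>   2.00 mm: contrast 0.083 -> resolved
#>   1.50 mm: contrast 0.242 -> resolved
#>   limiting resolution: 1.50 mm
#>   worst-case limiting resolution: 1.50 mm
```

The 2.0 and 1.5 mm sectors separate cleanly (contrast far below the 0.735
criterion), the 1.0 and 0.5 mm sectors do not, so this configuration
resolves 1.5 mm structure. The `"mouse"` configuration (0.5 mm tungsten
pinhole, 9x) resolves all six capillaries across their 0.5 mm gaps the
same way.

Every stage is also available as a shell command over YAML configs:

```sh
exec/pinspect predict  --config cfg.yaml
exec/pinspect run      --config cfg.yaml --seed 1 --out outdir/
exec/pinspect analyze  --recon outdir/recon.nii.gz \
                       --descriptor outdir/phantom.json --out report.json
```

Volumes are NIfTI (`.nii.gz`) or MetaImage (`.mhd/.raw`); projection sets
are multi-frame 32-bit TIFF with a JSON sidecar; every pipeline run writes
a manifest (config hash, seed, geometry fingerprint) that makes it
bit-reproducible.

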