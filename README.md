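# bladderdose

Monte Carlo light dosimetry for intracavitary photodynamic therapy (PDT) of
the bladder.

## The problem

Whole-bladder PDT for nonmuscle-invasive bladder cancer delivers green
(525 nm) light from an isotropic fiber emitter suspended in the water-filled
bladder, activating an instilled photosensitizer in the urothelium. The dose
actually received by the bladder wall is hard to predict because the bladder
acts as an integrating sphere — diffuse back-scatter multiplies the primary
irradiance by a factor that depends on the wall albedo
μs/(μs+μa) ≈ 0.97 at 525 nm — and because bladder shape and emitter
misplacement concentrate dose on the proximal wall. The package is for
biomedical-optics researchers and treatment planners who want to simulate
and analyze this situation quantitatively:

- **geometry** — synthetic bladder cavities (sphere, ellipsoid,
  superellipsoid, lobulated) with a finite wall and adipose backing,
  standing in for CT-derived patient meshes;
- **transport** — a C++ photon-packet Monte Carlo engine
  (Henyey–Greenstein scattering, absorption weighting, Russian roulette,
  Fresnel/Snell boundaries, per-packet RNG streams, exact energy ledger);
- **surface_dose** — dose-surface histograms (DSH): surface irradiance
  sorted descending against cumulative area fraction, with area-weighted
  summaries and a scale-free DSH distance;
- **sensors** — virtual models of three irradiance-monitoring devices
  (single cut-end fiber, triple angled-cut fibers, 12-sensor cos² cage),
  calibration, and treatment termination at a target radiant exposure of
  90 J cm⁻²;
- **selectivity** — the photodynamic-threshold model: with a specific
  uptake ratio SUR = uptake_tumor/uptake_normal and threshold doses T,
  treatment at depth d is selective iff
  (T_tumor/[PS]_tumor)·(φ(0)/φ(d)) < T_normal/[PS]_normal,
  allowing a fluence fall-off of SUR·T_normal/T_tumor ≈ 14.5, i.e. about
  2 mm of depth at an attenuation length of 750 µm;
- **pipeline** — config-driven studies: source displacement, void
  turbidity, and a wall-optical-property grid comparing sensor
  implementations.

## Worked example

A 48.5-ml spherical bladder, 2.5 W source displaced 1 cm dorsally, 2×10⁵
packets:

```r
library(bladderdose)
g       <- make_bladder_shape("sphere", volume_ml = 48.5)
patches <- tessellate_surface(g, n_patches = 200)
props   <- preset_properties("bladder_525nm")
dm <- run_transport(g, props, source_spec(c(0, -10, 0), power_mW = 2500),
                    patches, transport_config(n_packets = 2e5, seed = 1))
dm
#> <dose_maps> 200000 packets (seed 1), 200 patches
#>   mean irradiance 49.9 mW/cm^2; absorbed 1.000, escaped 0.000 (residual 5.3e-11)
build_dsh(dm, patches)
#> <dsh> 200 steps over 6431 mm^2; mean 49.9 mW/cm^2 (p10 83.7, p90 31.7, het 3.27)
```

The mean wall irradiance (49.9 mW cm⁻²) exceeds the bare inverse-square
value P/4πr² = 38.9 mW cm⁻² by the cavity multiplication factor (~1.27 at
the 525-nm wall albedo). The displaced source makes the dose heterogeneous:
the hottest 5% of the surface receives 3.27× the irradiance of the coldest
5% (a centred source gives ~1.1). The same run yields a fluence-depth
profile whose selectivity check, under the default threshold model
(SUR = 192.5, allowable fluence ratio 14.5), marks roughly the first 2 mm
of the wall as selectively treatable:

```r
prof <- fluence_profile_from_transport(dm, props)
chk  <- check_selectivity_profile(threshold_model(), prof, 2.5)
max(chk$depth_mm[chk$selective])
#> [1] 2.05
```

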