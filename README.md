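# voxreg

Parametric intensity-based image registration for 2-D and 3-D scalar
images, with the cohort-level machinery of template-based morphometry
studies — written for researchers who need a transparent, fully testable
registration stack on synthetic or real volumetric data (NIfTI / MetaImage)
without any external binaries.

## What it computes

Registration estimates a coordinate transform T<sub>μ</sub> from the fixed
image domain Ω<sub>F</sub> into the moving domain by minimizing

&nbsp;&nbsp;&nbsp;&nbsp;μ̂ = argmin<sub>μ</sub> 𝒞(I<sub>F</sub>, I<sub>M</sub>∘T<sub>μ</sub>) + w ℛ(T<sub>μ</sub>),

by stochastic gradient descent (μ<sub>k+1</sub> = μ<sub>k</sub> −
a<sub>k</sub> g<sub>k</sub>) inside a multi-resolution Gaussian-pyramid
loop. The derivative g<sub>k</sub> is an η-weighted sum over a fresh random
sample subset Ω̃<sub>F</sub> each iteration (η = 1/|Ω̃<sub>F</sub>|), with
each sample contributing ξ(·) · Jᵀ ∂I<sub>M</sub>/∂x; for the cubic
B-spline transform the d × N parameter Jacobian J has only P = (O+1)ᵈ
nonzero basis products per point (64 in 3-D), and only those are ever
computed or multiplied.

The pieces, each an exported module surface with its own tests:

* **Transforms** — translation, rigid, similarity, affine, cubic B-spline
  free-form deformation, composition; sparse parameter Jacobians, spatial
  Jacobian determinants, pointwise transformation averaging
  (U(x) = N⁻¹ Σ W<sub>j</sub>(x), identity included) and fixed-point
  numerical inversion.
* **Metrics** — MSD, normalized correlation (as 1 − NC²), Mattes mutual
  information (negated; 32-bin Parzen histogram), bending-energy penalty —
  all with analytic derivatives validated against finite differences, and a
  fork-join partitioned evaluation contract.
* **Pyramids** — Deriche-style recursive Gaussian smoothing (cost
  independent of σ), shrink/resample/off downsampling modes, and an
  emulated single-precision path for accelerator-accuracy comparisons
  (nRMSE < 10⁻⁶ against the double reference).
* **Resampler** — chunked initialize → transform-stages → interpolate
  pipeline, bit-identical for any chunk size; nearest / linear / B-spline
  1 & 3 interpolators.
* **Cohort analysis** — unbiased template construction (averaging +
  inversion), template-image averaging, majority-vote multi-atlas label
  fusion, Jacobian-determinant modulation (volume-conserving), region-wise
  volume features, z-scored feature tables, and the comparison measures
  nRMSE, deformation-field RMSE and Dice.
* **Synthetic fixtures** — deterministic generators for textured intensity
  volumes, ground-truth B-spline warps and Voronoi label atlases, so the
  whole pipeline runs with no downloaded data.

## Worked example

Register a synthetically warped 48² pair and compare the recovered
deformation field with the known ground truth:

```r
library(voxreg)

spec <- vx_fixture_spec(c(48, 48), seed = 7, warp_spacing = 12, warp_max_disp = 2)
pair <- vx_make_warped_pair(spec)        # fixed, moving, true_transform, true_field

cfg  <- vx_registration_config(resolutions = 2, iterations = 80, samples = 800,
                               grid_spacing = 6, seed = 1)
res  <- vx_register(pair$fixed, pair$moving, cfg)

pts  <- vx_voxel_to_world(vx_geometry_of(pair$fixed),
                          as.matrix(expand.grid(0:47, 0:47)))
rec  <- array(vx_map_point(res$transform, pts) - pts, c(48, 48, 2))
cat(sprintf("initial field RMSE: %.3f mm\n",
            vx_field_rmse(pair$true_field, array(0, dim(pair$true_field)))))
cat(sprintf("final field RMSE:   %.3f mm\n", vx_field_rmse(rec, pair$true_field)))
cat(sprintf("final MSD cost:     %.2f\n", tail(res$log$value, 1)))
```

```
initial field RMSE: 0.782 mm
final field RMSE:   0.279 mm
final MSD cost:     31.36
```

The initial RMSE is the misalignment the synthetic warp introduced; after
the similarity → affine → B-spline staged registration the residual field
error is well below one voxel (1 mm spacing here), and the remaining MSD
reflects interpolation noise on the 0–1000 intensity scale. `res$transform`
is a composite transform (`vx_write_transform()` serializes it), `res$log`
holds one row per iteration, and `res$resampled` is the moving image pulled
onto the fixed grid.

A command-line interface wraps the same functions
(`inst/cli/voxreg register|resample|fixtures|compare`), driven by a plain
`Key = value` parameter file.

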