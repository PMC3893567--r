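---
title: "Parametric intensity-based registration in voxreg: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric intensity-based registration in voxreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxreg)
```

## The registration model

Registration estimates a parametric coordinate transform $T_\mu$ from the
fixed image domain into the moving image domain by minimizing a cost

$$\hat\mu = \arg\min_\mu \; \mathcal{C}\big(I_F, I_M \circ T_\mu\big)
  \; + \; w \, \mathcal{R}(T_\mu),$$

with $I_F$ the fixed image, $I_M$ the moving image, $\mathcal{C}$ a
similarity metric and $\mathcal{R}$ an optional bending-energy regularizer
with weight $w$ (default 0). Optimization is plain gradient descent,
$\mu_{k+1} = \mu_k - a_k\, g_k$, embedded in a coarse-to-fine
multi-resolution scheme over Gaussian pyramid levels.

The cost derivative is never evaluated over the full image. Each iteration
draws a fresh uniform random subset $\tilde\Omega_F$ of fixed-domain points
(default 2000) and forms the derivative as the $\eta$-weighted sample sum,
$\eta = 1/|\tilde\Omega_F|$, of per-sample terms: a scalar intensity factor
$\xi(\cdot)$ (for mean squared difference, $\xi = I_F(x) - I_M(T(x))$) times
the product $J^\top \,\partial I_M/\partial x$ of the transposed parameter
Jacobian with the moving-image spatial gradient. Samples whose mapped point
leaves the moving domain are dropped and $\eta$ is recomputed over the
included count; this avoids boundary-artifact gradients at the price of a
mild discontinuity of the cost when samples cross the boundary.

### Transforms and the sparse Jacobian

Six transform kinds are supported: translation, rigid (Euler angles; Z-Y-X
composition in 3-D), similarity (rigid plus one isotropic scale), affine,
cubic B-spline free-form deformation, and composition. For the B-spline,
the mapped point depends on only $P = (O+1)^d$ control points ($O = 3$
cubic: 64 in 3-D), so the $d \times N$ parameter Jacobian is block-diagonal
with identical rows of $P$ tensor-product basis values; `voxreg` stores and
multiplies only those $P$ values (`vx_parameter_jacobian()`,
`vx_sparse_gradient_product()`), making the per-sample cost $O(dP)$ rather
than $O(dN)$. The basis products satisfy partition of unity, which the test
suite checks at random interior points.

Stage chaining uses function composition: a later stage is appended as the
outermost member of a composite and is the only member optimized, so a
similarity or affine pre-alignment stays frozen under the subsequent
B-spline stage. The B-spline control lattice is placed to give full basis
support over the (inner-chain-mapped) fixed domain plus one spacing of
margin, and is refined dyadically between resolutions with the two-scale
(knot-insertion) weights $\tfrac18(1,4,6,4,1)$ — exact up to rounding, which
the tests pin at $10^{-6}$ mm. Non-dyadic refinement falls back to a
separable least-squares fit and reports its residual; the standard staging
never uses it.

### Metrics

* **MSD** — mean squared intensity difference; the reference metric for
  mono-modal synthetic experiments and the default.
* **NC** — normalized correlation, returned as $1 - \mathrm{NC}^2$ so that
  all metrics are minimized; invariant to affine intensity maps of the
  moving image.
* **MI** — Mattes-style mutual information, returned negated. The joint
  histogram uses 32 bins, a zero-order window on the fixed intensity and a
  cubic B-spline Parzen window on the moving intensity; bin edges are fixed
  from the global intensity ranges so the cost is smooth in $\mu$. These
  constants are choices of this package (the number of bins and window
  orders are the ones most implementations default to) and are exposed in
  the configuration.
* **Bending energy** — the sample mean of the squared Frobenius norm of the
  second spatial derivative of $T$; exactly annihilated by globally affine
  displacements, which the tests verify both for the value and the
  derivative.

All four derivatives are validated against central finite differences at
relative tolerance $10^{-4}$; this oracle is the strongest single check in
the suite because it exercises the whole chain (B-spline support, sparse
Jacobian, interpolator gradients, histogram windows) at once.

### Fork-join evaluation

`vx_evaluate_partitioned()` mirrors a multi-threaded derivative loop: the
included samples are split into $T$ contiguous partitions whose sizes differ
by at most one, one partial derivative is produced per partition, and
`vx_join_partials()` combines them as a count-weighted sum times $\eta$.
Global sufficient statistics (means for NC, the joint histogram for MI) are
shared across partitions, so the result for any $T$ equals the $T=1$ result
up to floating-point reassociation of the partition sums; the tests bound
this at $10^{-12}$ per component (mixed relative/absolute, since components
whose contributions nearly cancel sit at raw rounding level). The package
executes partitions serially — the contract, not device parallelism, is the
tested artifact.

## Gaussian pyramids

Smoothing uses a recursive (IIR) approximation of Gaussian convolution in
the Deriche family: the Gaussian is approximated by two exponentially damped
cosine/sine pairs, giving a 4th-order causal + anti-causal recursive filter
whose cost is independent of sigma. The filter coefficients are assembled
numerically from the pole/residue form and normalized to unit DC gain, so
constants are preserved exactly; boundaries use edge-value extension with
steady-state initialization. Against a dense FIR oracle (truncated at
$8\sigma$) the relative L2 error on impulses is below $10^{-3}$ for
$\sigma \in \{1, 2, 4\}$ — the approximation order and boundary rule are
design choices pinned by that tolerance. Sigma is interpreted in voxel
units. Smoothing is separable (x, then y, then z) and scan lines within an
axis are independent; `vx_max_local_line_length()` is the planning utility
for the line-buffer memory bound of accelerator implementations (three
line-sized buffers; 16 kB of 4-byte elements bounds lines at 1365 samples).

Three downsampling modes are provided: `off` (smooth only), `shrinker`
(every factor-th voxel starting at index 0, origin unchanged) and
`resampler` (linear resampling onto a grid with factor-scaled spacing). The
classic schedule pairs factors 8, 4, 2, 1 with sigmas 4, 2, 1, 0.

### The emulated single-precision path

Accelerated implementations typically compute in 32-bit floats. To make
that comparison testable without a device, pyramid smoothing and resampling
accept `precision = "single"`, which rounds the data arrays to IEEE
binary32 after each pass (input, causal output, anti-causal output, sum;
mapped-point buffers and interpolated values in the resampler). The scalar
filter constants are computed once and kept at host (double) precision —
rounding them perturbs the transfer function itself rather than emulating
arithmetic precision, and is not what a host-precomputed-constant
implementation does. Under this model the double/single nRMSE,
$\sqrt{\sum (I_\mathrm{ref} - I_\mathrm{acc})^2 / \sum I_\mathrm{ref}^2}$,
is about $4\times10^{-8}$ per level on the 100³ schedule, well inside the
$10^{-6}$ contract; nearest-neighbor resampling may additionally flip
isolated voxels where coordinate rounding crosses a half-integer, and the
tests assert such flips are isolated rather than clustered.

## Resampling

`vx_resample()` is a three-stage pipeline over output chunks: (1) fill a
buffer with the chunk's voxel-center world coordinates, (2) push the buffer
through each transform stage, innermost first, so it ends up holding
$T_n(\dots T_1(x))$, (3) interpolate the moving image at the buffered
points and write the chunk. Chunking bounds the intermediate
deformation-field memory (default $2^{20}$ points) and is pure memory
management: all per-point arithmetic uses explicit fixed-order per-axis
accumulation (no BLAS reductions), so results are bit-identical for any
chunk size — asserted down to one-voxel chunks. Interpolators: nearest
neighbor (round half away from zero, componentwise), linear (whose analytic
gradient is the fast path used by the metric), and B-splines of order 1 and
3; the cubic interpolator prefilters the image into B-spline coefficients
with the standard recursive filter (pole $\sqrt3 - 2$, mirror boundary,
exact periodic initialization).

## Cohort-level operations

For a cohort $I_1,\dots,I_N$, pairwise transforms $W_{i,j}$ (subject $i$
fixed) define the unbiased template construction: $U_i(x) = \frac1N \sum_j
W_{i,j}(x)$ with the identity $W_{i,i}$ included, and $V_i = U_i^{-1}$
mapping template space to subject $i$. The average is evaluated on the
caller's voxel grid and stored as a dense, linearly interpolated
displacement field — transforms of any kind can then be averaged and the
result stays closed under further averaging and numerically invertible. The
inverse is found by damped fixed-point iteration $v \leftarrow v - (U(x+v) -
x)$ (damping 1, halved when the worst residual grows), default tolerance
0.01 mm, cap 50 iterations, with the achieved residual reported and
non-convergence raised as an error carrying the worst point. The template
image is the voxelwise mean of the images pulled through their $V_i$.

Label fusion is plain majority voting with ties broken toward the smallest
label — a convention that makes fusion invariant to atlas order. Modulation
multiplies a warped probabilistic map by the spatial Jacobian determinant of
its transform, preserving integrated tissue volume for smooth invertible
warps (conservation within 1% on the synthetic warps used in testing;
negative determinants are counted and reported as a folding warning).
Region-wise features divide label-summed probabilistic volume by a
normalizing volume, and `vx_zscore_features()` normalizes feature columns
with mean and population standard deviation fitted on a training subset.
Comparison measures — nRMSE, deformation-field RMSE (optionally within a
mask) and the Dice coefficient (defined as 1 when both sets are empty) —
are each validated against naive per-voxel loops.

## Optimization: gains, scales and robustness

Adaptive step-size estimation (as in adaptive stochastic gradient descent
optimizers) is outside this package's scope, so the
package uses the classical decaying gain $a_k = a/(A + k)^\alpha$ with
defaults $A = 20$, $\alpha = 0.602$. A fixed base gain $a$ cannot serve
across metrics, intensity scales and mixed parameter units (radians vs mm),
so by default $a$ is calibrated at the start of each resolution such that
the first update moves the scaled parameters by `step_target` (default 0.4
mm), using classical parameter scales: rotation angles and affine matrix
entries are scaled by the domain radius, translations and B-spline
coefficients are already metric. Because that calibration can land on an
unrepresentative first gradient (small near an optimum), every update is
additionally capped at `2 * step_target` mm of scaled parameter motion — a
minimal trust region that removed the only divergence observed during
development. A non-finite derivative is retried once with a fresh sample
set, then aborted with context. With `threads = 1` and a fixed seed the
whole registration is bit-reproducible; sampling uses a counter-based
stream keyed by (seed, iteration), so iteration-k sample sets are
reproducible without sequential RNG state.

## Synthetic fixtures and what they do (not) show

`vx_make_image()` draws ~80 signed anisotropic Gaussian blobs (3–10% of the
extent) plus a gentle linear bias, rescaled to [0, 1000]: smooth images with
gradient information essentially everywhere, emulating tissue-like texture.
That choice matters: with sparse texture the aperture problem leaves the
true field unobservable in flat regions, and no algorithm could recover it.
`vx_make_warped_pair()` draws a random B-spline warp with control-point
displacements bounded below half the warp grid spacing (guaranteeing
invertibility), tapered to zero at the lattice border; the moving image is
the fixed image resampled through the warp's numerical inverse, so that the
registration target is the stored ground-truth transform itself.
`vx_make_label_atlas()` builds Voronoi labelings warped by small random
deformations.

The recovery experiment registers a 64³ pair (maximum displacement 3
voxels) with the similarity → affine → B-spline staging, 3 resolutions,
dyadic grid refinement to 8 mm, 150 iterations and 2000 samples per
iteration, and evaluates deformation-field RMSE inside a central-ellipsoid
analysis mask — the synthetic counterpart of computing RMSE within the
brain mask used for registration, which is the standard protocol for this
measurement. Typical results are ~0.1 mm final RMSE from ~1 mm initial
(sub-voxel, roughly a tenth of the misalignment). Problem sizes throughout
(100³ pyramids, 64³ recovery, 32³ invariance checks, 2-D 32² derivative
oracles) were chosen so the full suite exercises study-scale arrays while
remaining comfortable on a single CPU.

What passing these tests does **not** show: robustness to MRI artifacts
(bias fields, noise, partial volume), multi-modal alignment quality (MI is
validated analytically, not on multi-modal data), behavior under large
rotations (initialization is identity), or the statistical performance of
downstream classification, which is outside the package's scope.

## Known limitations

* Gradient descent with a decaying gain needs more iterations than adaptive
  step-size schemes; the defaults favor robustness over speed.
* Transform averaging and inversion are grid-sampled; fidelity between
  voxels is limited by linear interpolation of the displacement field.
* The single-precision path is an emulation of float arithmetic at pass
  granularity, not an exact replay of any particular device.
* Only scalar 2-D/3-D images; no DICOM, time series or tensor voxels.
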