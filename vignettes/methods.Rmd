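---
title: "Methods: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by `mmreg`, the
numerical choices behind it, and the places where the design was genuinely
open and a decision had to be made. It states no empirical result beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## Transformation model

The warp is a small-deformation displacement field: `phi(x) = x + d(x)`
with `d` a uniform cubic-B-spline field, one independent coefficient set
per displacement direction, all three directions sharing one knot grid.
Cubic B-splines give C2-continuous warps defined everywhere (not only at
voxel centres), closed-form spatial derivatives, and compact support, which
makes the Gauss-Newton Hessian sparse with a fixed structure: entry
`(i, j)` can be nonzero only when splines `i` and `j` overlap in support
(knot offset at most 3 per axis for cubics, all nine direction blocks
present).

*Knot-grid margin.* The stored splines are exactly those whose support
overlaps the warp domain. For cubic splines this places the first and last
knot one knot spacing outside the domain on each side — the smallest set
consistent with the overlap rule — so every interior point lies in the
support of exactly four splines per axis.

*Coordinates.* Voxel coordinates are 0-based and continuous; image affines
map voxels to world mm (NIfTI convention); displacements are stored in mm
in the warp space's world frame. FLIRT-format affine matrices are
interpreted in FSL's scaled-voxel convention (voxel index times voxel
size, x flipped when the voxel-to-world affine has positive determinant);
the conversion is unit-tested against a hand-computed example.

*On-disk warps.* Warps are written as 4D NIfTI displacement volumes
(three volumes, relative mm displacements, warp-space affine in the
header). Whether downstream consumers expect relative or absolute
conventions is not decidable from first principles; relative was chosen
and is documented here, and the dense-field reader (`warp_volume`)
evaluates between voxel centres by interpolating splines through the
stored field.

## Cost terms

**Scalar (MSE).** `C_s = mean over the domain of m(x) w(x) (f(x) -
g(phi(x)))^2`. Both images are first rescaled so their robust mean is 1.
The "robust mean" is the median over the mask support; without a mask the
support is the set of voxels above 1 % of the 99th-percentile intensity,
which keeps empty background from dragging the median toward zero. The
moving image is sampled by exact interpolating cubic splines (prefilter by
a direct banded solve with whole-sample mirror boundaries — exact at the
nodes to machine precision). Samples that fall outside the moving volume
get zero weight rather than fabricated intensities.

**Tensor (mean squared Frobenius norm).** Per voxel the reference tensor
is rotated as `R F R^T` with the finite-strain rotation `R = (J J^T)^(-1/2)
J` (computed as the orthogonal polar factor `U V^T` of the SVD of `J`); the
moving tensor is interpolated component-wise (trilinear — the cost is
defined on raw elements, so no log-Euclidean machinery is used) at
`phi(x)`. The squared Frobenius norm over all nine elements is exactly the
sum of nine per-element squared errors, so the six stored components enter
with multiplicities (1, 2, 2, 1, 2, 1) and the term fits the Gauss-Newton
machinery directly. Interpolated tensors are *not* projected back to
positive definite: the cost needs only the elements. No intensity scaling
or bias field applies to tensors (they are quantitative).

The Gauss-Newton derivatives include both the displacement effect (via the
moving-tensor gradients) and the rotation effect. The derivative of the
polar factor with respect to the Jacobian uses the closed form obtained
from `J = R S`: `dR = R [w]_x` with
`w = (tr(S) I - S)^{-1} axial(R^T dJ - dJ^T R)`. Its correctness contract
is the central-finite-difference oracle in the test suite (relative error
below 1e-3 for the full gradient including rotation, 1e-4 for the other
terms).

*Units and weighting.* The tensor term's default weight of 1 presumes
tensor elements of order 1 (e.g. μm²/ms). FSL `dtifit` volumes carry mm²/s
values of order 1e-3, making the squared-error term of order 1e-6 relative
to a robust-scaled image term; with such data `lambda_tensor` should be of
order 1e6 (used by the package's own phantom experiments). This is a unit
conversion, not a tuning parameter.

*Where `R` is evaluated.* When the tensor grid differs from the warp
space, `R` is evaluated at the voxel centres of the current sampling grid
(not at the interpolation targets); with matched grids the two coincide.

**Regularisation.** `C_r` is the mean of `sum_i (log s_i(J))^2` over the
singular values of the local Jacobian. It is zero exactly for locally
rigid motion, symmetric in expansion versus compression, and diverges as
any singular value approaches 0 or infinity, so any step that folds the
warp has infinite cost and is rejected — accepted warps are always
diffeomorphic. For Gauss-Newton the three per-sample residuals are `log
s_i`, giving an exact sum-of-squares structure; `d log s_i / dJ = u_i
v_i^T / s_i` from the SVD. Repeated singular values make the SVD factors
non-unique, but the penalty depends only on the values; the subgradient
the SVD returns is used and the finite-difference oracle bounds the
behaviour in practice. The penalty is sampled at the voxel centres of the
current pyramid level, the same grid as the image terms.

**Symmetrisation.** Every cost term — image terms and the regulariser —
is multiplied per voxel by `1 + |J|`, which accounts for the total volume
in both images that each grid sample represents and approximately
symmetrises the objective under swapping reference and moving roles (a
flag disables it for ablation; the paired phantom experiment in the
acceptance suite measures its effect on inverse-consistency error). The
weight is treated as a fixed cost weighting within each Gauss-Newton step:
it is recomputed from the current warp every iteration but not
differentiated, which preserves the sparse `J^T J` Hessian structure.
Step acceptance uses the true (reweighted) cost, so monotone descent is
preserved.

## Bias field

MRI transmit/receive inhomogeneity is modelled as a multiplicative field
on the reference image only, parametrised as `exp(s(x))` with `s` a cubic
B-spline field on its own (much coarser) knot grid — the log
parametrisation guarantees positivity without constraints. It is estimated
with the warp held fixed by Gauss-Newton on `bending_weight * bending(s) +
MSE(exp(s) f, g(phi))`, where the bending energy is the mean squared sum
of second partials of `s` at voxel centres (closed-form spline second
derivatives, mm^-2). Bias and warp estimation are interleaved (never
jointly optimised); the default bias knot spacing is 8x the finest warp
knot spacing and the bending weight is set per image pair.

## Optimiser

Damped Gauss-Newton: solve `(H + mu diag(H)) dw = -grad` by
Jacobi-preconditioned conjugate gradients (relative tolerance 1e-6, at
most 500 iterations — the sparse Hessian is never factorised), accept the
step only if the true total cost decreases, multiply `mu` by 10 on
rejection and divide by 10 on acceptance, starting from `mu = 1e-3 *
mean(diag H)`. A level converges when the relative cost decrease is below
1e-4 for two consecutive accepted steps, with at most 20 steps per level.
These damping and convergence constants are standard practice choices.

The pyramid is defined by warp knot spacing and image smoothing only. The
default schedule runs knot spacings 16, 8, 4, 2, 1 mm (down to the
requested final resolution) with FWHM a quarter of the knot spacing and
regularisation weight 0.18 at 1 mm, divided by 0.85 per doubling of the
knot spacing (0.21 at 2 mm, 0.25 at 4 mm, reported to two decimals). The
cost-sampling step per level treats the Gaussian kernel as a low-pass
filter: a kernel of full width `fwhm` suppresses content above about
`1/fwhm` cycles/mm, so a step of `fwhm/2` samples the smoothed image
alias-free; the step is clamped to `[knot/4, knot]` (and never finer than
the native voxel). The `fwhm/2` constant is the package's concretisation
of the aliasing principle; an aliasing test on a synthetic sinusoid backs
it.

Between levels the coarse warp is carried to the finer knot grid by
least-squares projection of its displacement field sampled on the level
grid (with a tiny relative ridge, 1e-8 of the mean Gram diagonal, to pin
margin splines that have almost no support in the domain). If the
projection overshoots into a folded configuration near the margins, the
coefficients are shrunk by 10 % steps until feasible — a safeguard that in
practice triggers only for extreme warps.

Only the explicit sparse Gauss-Newton Hessian is implemented. A
lower-memory Hessian approximation would only pay off on hardware-limited
systems; at the problem sizes this package targets the explicit sparse
form fits comfortably in memory, so a single optimiser variant keeps the
code simpler and the tests sharper.

Everything is deterministic: no stochastic sampling or initialisation
anywhere; two runs with identical inputs differ only by floating-point
reduction order (the test suite asserts maximum displacement differences
below 1e-3 mm, far looser than observed).

## Evaluation metrics

Jaccard index (intersection over union) and modified Hausdorff distance
(the larger of the two mean directed surface distances). Surfaces are
discretised as region voxels with at least one face-adjacent (6-connected)
background neighbour, and distances are Euclidean between voxel centres —
one of several defensible discretisations of a surface distance; the
brute-force double-loop oracle in the tests pins the implementation to
this definition exactly.

Tensor similarity: overall tensor overlap (OVL), and eigenvector
similarities weighted by the Westin linear and planar shape coefficients
CL and CP computed from the *reference* field only, with vector similarity
as the magnitude of the dot product. Zero-trace tensors inside the mask
are excluded and counted. Distortion: the 5th–95th percentile range of
`log |J|` (volume change) and the mean cube-volume aspect ratio
`(s_max^3 / (s_1 s_2 s_3))^(1/3)` (pure shape change, always ≥ 1, exactly
1 for scaled rotations).

`resample_tensors` reorients by the *inverse* finite-strain rotation
(conjugation by `R^T`): because the cost matches `R F R^T` against
`G(phi(x))`, only the inverse rotation makes a perfectly registered moving
volume reproduce the reference — which is what the OVL/CLV1 recovery
checks require. Reorientation is an orthogonal conjugation, so eigenvalues
are preserved exactly (asserted to 1e-10).

## Synthetic phantoms

The generators emulate just enough structure to exercise every code path:
a multi-blob scalar volume (disjoint Gaussian blobs inside a spherical
mask, so the label volume coincides exactly with the analytic blob
supports), a tensor field with a prolate tract along a circular arc
(eigenvalues 1.7/0.3/0.3 × 1e-3 mm²/s, first eigenvector along the local
tangent), an oblate sheet (1.2/1.2/0.3 × 1e-3) and isotropic background
(0.7e-3) — a physiological eigenvalue range, SPD everywhere by convex
combination — and a smooth random B-spline ground-truth warp scaled to a
requested maximum displacement and verified to keep `|J| > 0.2`. The
moving subject is simulated by pulling each volume through the inverse
warp (fixed-point inversion, tolerance 1e-3 voxel), with tensors rotated
so that the moving data satisfy the cost model exactly at the true warp.
Additive Gaussian noise defaults to 2 % of the clean intensity range
(scalar only): enough to be nontrivial, small enough to keep the MSE
well-conditioned.

What the phantoms do *not* emulate: MR physics (partial volume, Rician
noise, susceptibility distortion), anatomical variability beyond smooth
warps, crossing fibres, or intensity nonstationarity other than the
explicit bias field. Passing the recovery tests therefore demonstrates the
correctness of the estimation machinery under the model's own assumptions,
not performance on real brains.

*Problem sizes in the tests.* Cost oracles run on ≤16³ instances; scalar
warp recovery uses the 48³ phantom with a 4-voxel ground-truth warp and a
16/8/4 mm pyramid; the tensor-driven experiment uses a 32³ phantom to
8 mm; the paired inverse-consistency comparison registers a 24³ phantom in
both directions with the symmetrising weight on and off (four
registrations); bias recovery uses 24³. These sizes were chosen as the
smallest that still make each property measurable.

## Known limitations and open-edge decisions

* The configuration file is YAML rather than TOML (no TOML parser among
  the package's dependencies); the structure mirrors the pyramid schedule
  exactly.
* Only finite-strain reorientation is provided (for both the cost and
  evaluation resampling); preservation-of-principal-direction is not
  implemented.
* The nonzero-per-Hessian-row count is bounded by the support-overlap rule
  and tested against a brute-force pairwise oracle rather than any printed
  constant (for cubic splines in 3D the bound is 3 x 7^3 = 1029 per row).
* Masks are linearly interpolated when pulled through the warp; soft masks
  are supported but not renormalised.
* The inverse of a cubic-B-spline warp is generally not itself a
  B-spline field; `ic_error` therefore measures inverse consistency by
  numerical composition, and `invert_warp_at` is a fixed-point
  approximation valid for moderate, diffeomorphic warps.
* Affine initialisation is expected from outside (FLIRT-format matrices);
  the package estimates only the nonlinear part.
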