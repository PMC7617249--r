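# mmreg: multimodal nonlinear image registration with B-spline warps

`mmreg` estimates a smooth, invertible spatial mapping (a *warp*) between
two brains (or any pair of 3D datasets) using any combination of scalar
volumes (e.g. T1-weighted MRI) and diffusion-tensor volumes. It is aimed at
neuroimaging researchers who need template registration that uses the
orientational information in DTI data, with explicit control over how much
the warp distorts volume and shape, plus the evaluation metrics commonly
used to benchmark such registrations.

## The model

The deformation is a small-deformation displacement field parametrised by
uniform cubic B-splines, one coefficient set per displacement direction:

    phi(x, w) = x + W B(x)

The warp minimises the total cost

    C_tot(w) = sum_s lambda_s C_s + sum_t lambda_t C_t + lambda_r C_r

over the warp domain, where

* `C_s` is the mean squared intensity error between the (robustly
  intensity-scaled, optionally bias-corrected) reference image and the
  moving image sampled at `phi(x)`;
* `C_t` is the mean squared Frobenius norm between the reference tensors,
  reoriented per voxel by the finite-strain rotation
  `R = (J J^T)^(-1/2) J` of the local Jacobian `J`, and the moving tensors
  interpolated at `phi(x)`;
* `C_r` is the mean of `sum_i (log s_i(J))^2` over the three singular
  values of `J` — zero for locally rigid motion, infinite at folding, so
  accepted warps are always diffeomorphic;
* every term is weighted per voxel by `1 + |J|`, which approximately
  symmetrises the cost with respect to swapping the two images.

Because cubic B-splines have compact support, the Gauss-Newton Hessian of
every term is sparse and predictably patterned (structurally nonzero only
for spline pairs whose supports overlap; at least 99.9 % sparse beyond 10^6
parameters). Optimisation is damped Gauss-Newton (Levenberg-Marquardt) with
a Jacobi-preconditioned conjugate-gradient solver, run coarse-to-fine over
a pyramid defined by warp knot spacing and image smoothing, with
subsampling chosen so the smoothed images stay alias-free. An optional
multiplicative bias field on the reference image (log-parametrised
B-splines, bending-energy penalised) is estimated interleaved with the
warp.

The package also implements the standard evaluation suite: Jaccard index
and modified Hausdorff distance for label overlap, overall tensor overlap
(OVL) and the linear/planar-shape-weighted eigenvector similarities (CLV1,
CPV3), and distortion measures (5th–95th percentile range of log |J|, mean
cube-volume aspect ratio), plus a seeded synthetic phantom generator so
every component can be exercised without any imaging data.

## Worked example

Generate a 48^3 phantom with a known diffeomorphic ground-truth warp
(maximum displacement 4 voxels), simulate the moving subject, register it
back, and measure the recovery:

```r
library(mmreg)

spec <- phantom_spec(seed = 1)          # 48^3, 1 mm, 4-voxel warp
ph   <- make_scalar_phantom(spec)
gt   <- make_ground_truth_warp(spec)
mov  <- warp_forward(ph, gt)

fit <- mmreg(ref_scalar = ph$image, mov_scalar = mov$image,
             ref_mask = ph$mask, mov_mask = mov$mask,
             schedule = default_schedule(4))
print(fit)
#> Multimodal B-spline registration fit
#>   warp: 15 x 15 x 15 splines per direction at 4 x 4 x 4 mm knots
#>   mean |displacement|: 1.149 mm (max 2.084 mm)
#>   final total cost: 0.0032726 over 35 accepted steps
#>   min Jacobian determinant: 0.843 (0% non-positive)

vox  <- space_grid(fit$space)
msk  <- as.numeric(ph$mask$data) > 0.5
err  <- warp_displacement(fit$warp, vox) - warp_displacement(gt, vox)
sqrt(mean(rowSums(err[msk, ]^2)))       # masked displacement RMSE (mm)
#> [1] 0.4066788
```

The fitted warp recovers the hidden deformation to ~0.41 voxel RMSE inside
the mask and never folds (minimum Jacobian determinant 0.84). `coef()`
returns the spline coefficients, `predict()` warps coordinates or resamples
the moving scalar/tensor volumes into reference space, `residuals()`
returns the intensity residual volume, and `plot()` shows the per-level
cost trace.

A thin command-line front end (`inst/scripts/mmreg`) wraps the same
functions for shell use: `mmreg register`, `mmreg phantom`,
`mmreg metrics`, `mmreg icerror`, with NIfTI volumes, FLIRT-format affine
text files and a YAML pyramid configuration.

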