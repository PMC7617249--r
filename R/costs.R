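## Scalar image cost: masked, symmetrisation-weighted mean squared error
## between the reference image and the warped moving image, with
## Gauss-Newton gradient / sparse Hessian assembly.

## ---- shared sampling helpers --------------------------------------------

## Cubic-spline sample of a scalar image at world points; optionally returns
## the intensity gradient in world (mm) coordinates.
## Returns value, grad (N x 3 or NULL), inside.
.sample_scalar <- function(img, world, space, gradient = FALSE, sc = NULL) {
  A <- world_to_imgvox(img, space)
  vox <- xform_pts(A, world)
  if (is.null(sc)) sc <- spline_prep(img$data)
  v <- spline_sample(sc, vox)
  gr <- NULL
  if (gradient) {
    gr <- matrix(0, nrow(world), 3)
    B <- A[1:3, 1:3]                     # d(vox)/d(world)
    for (a in 1:3) {
      dv <- c(0L, 0L, 0L)
      dv[a] <- 1L
      ga <- spline_sample(sc, vox, deriv = dv)$value
      for (cc in 1:3) gr[, cc] <- gr[, cc] + ga * B[a, cc]
    }
  }
  list(value = v$value, grad = gr, inside = v$inside)
}

## Linear sample of a nonnegative weight volume at world points; outside the
## mask's grid the weight is zero.
.sample_weight <- function(mask, world, space) {
  if (is.null(mask)) return(rep(1, nrow(world)))
  vox <- xform_pts(world_to_imgvox(mask, space), world)
  v <- trilinear_sample(mask$data, vox)
  w <- v$value
  w[!v$inside] <- 0
  pmax(w, 0)
}

## Symmetrisation weight 1 + |det J| at given warp-space voxel points.
sym_weight_at <- function(warp, vox) {
  J <- warp_jacobian(warp, vox)
  1 + abs(.det3(J))
}

## Determinant of row-wise column-major 3x3 matrices.
.det3 <- function(J) {
  J[, 1] * (J[, 5] * J[, 9] - J[, 8] * J[, 6]) -
    J[, 4] * (J[, 2] * J[, 9] - J[, 8] * J[, 3]) +
    J[, 7] * (J[, 2] * J[, 6] - J[, 5] * J[, 3])
}

## Assemble gradient and sparse GN Hessian from engine inputs.
.gn_assemble <- function(grid, vox, terms, fields, resid, active, ndir = 3L) {
  orders <- lapply(1:3, function(ax) sort(unique(terms[, 2 + ax])))
  wl <- lapply(1:3, function(ax) {
    lapply(0:2, function(o) {
      if (!(o %in% orders[[ax]])) return(NULL)
      dv <- c(0L, 0L, 0L)
      dv[ax] <- as.integer(o)
      warp_axis_weights(grid, vox, deriv = dv)[[ax]]$W
    })
  })
  ax0 <- warp_axis_weights(grid, vox)
  cells <- cbind(ax0[[1]]$first, ax0[[2]]$first, ax0[[3]]$first)
  res <- cpp_gn_engine(cells, wl, terms, fields, resid, grid$counts,
                       as.integer(ndir), active)
  n <- ndir * grid$M
  H <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x, dims = c(n, n))
  list(grad = res$grad, H = H)
}

## ---- robust intensity scaling -------------------------------------------

#' Robust global intensity scale of an image
#'
#' Returns the factor that makes the robust mean (the median over the mask
#' support) of the image equal to one.  Reference and moving images are
#' scaled independently before the MSE cost is evaluated, so that global
#' linear intensity differences are not mistaken for misalignment.
#'
#' @param img an [image3d()].
#' @param mask optional [image3d()] of nonnegative weights on the same grid;
#'   voxels with positive weight define the support.  Without a mask, the
#'   support is the set of voxels above 1 percent of the 99th-percentile
#'   intensity, which keeps empty background out of the estimate.
#' @return a positive scalar factor.
#' @export
robust_scale <- function(img, mask = NULL) {
  v <- as.numeric(img$data)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask$data) == dim(img$data)))
    v <- v[as.numeric(mask$data) > 0]
  } else {
    hi <- stats::quantile(v, 0.99, names = FALSE)
    if (hi > 0) v <- v[v > 0.01 * hi]
  }
  if (length(v) == 0) stop("mask has no support: no voxels to scale on")
  m <- stats::median(v)
  if (m <= 0) m <- mean(abs(v[v != 0]))
  if (!is.finite(m) || m <= 0)
    stop("cannot derive an intensity scale from an all-zero image")
  1 / m
}

## ---- MSE cost ------------------------------------------------------------

## Shared evaluation core: samples everything on the voxel grid of `space`
## (default: the warp's own space) and returns the pieces needed by both the
## cost and its derivatives.
.mse_parts <- function(f, g, warp, ref_mask, mov_mask, sym_weight, space,
                       gradient = FALSE, f_sc = NULL, g_sc = NULL,
                       bias = NULL) {
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  world0 <- xform_pts(base$affine, vox)
  phi <- apply_warp(warp, vox)
  fs <- .sample_scalar(f, world0, base, sc = f_sc)
  gs <- .sample_scalar(g, phi, base, gradient = gradient, sc = g_sc)
  w <- .sample_weight(ref_mask, world0, base) *
    .sample_weight(mov_mask, phi, base)
  w[!gs$inside] <- 0
  if (all(w == 0))
    stop("no overlap between the images inside the warp domain")
  sw <- if (is.null(sym_weight)) sym_weight_at(warp, vox) else
    rep_len(sym_weight, nrow(vox))
  fval <- fs$value
  if (!is.null(bias)) fval <- fval * evaluate_bias(bias, vox)
  list(vox = vox, w = w, sw = sw, f = fval, g = gs$value, ggrad = gs$grad,
       N = nrow(vox))
}

#' Mean-squared-error cost between a reference and a warped moving image
#'
#' Computes the masked, symmetrisation-weighted mean squared intensity
#' difference over the warp domain:
#' \deqn{C_s = \frac{1}{N}\sum_x m(x)\,\omega(x)\,(f(x) - g(\phi(x)))^2}
#' where \eqn{m} is the combined mask weight, \eqn{\omega} the
#' inverse-consistency weight \eqn{1 + |J|} (or a supplied factor), and the
#' moving image is sampled by cubic-spline interpolation at the warped
#' positions.  Images should be intensity-scaled first (see
#' [robust_scale()]).
#'
#' @param f,g reference and moving [image3d()] objects.
#' @param warp a [warp_field()].
#' @param ref_mask,mov_mask optional nonnegative weight volumes
#'   ([image3d()]) in the space of their respective images.
#' @param sym_weight `NULL` to compute the `1 + |J|` weight from the warp,
#'   or a numeric factor / per-voxel vector (use `1` to disable).
#' @param space optional sampling [warp_space()] (defaults to the warp's).
#' @return scalar cost value.
#' @export
mse_cost <- function(f, g, warp, ref_mask = NULL, mov_mask = NULL,
                     sym_weight = NULL, space = NULL) {
  p <- .mse_parts(f, g, warp, ref_mask, mov_mask, sym_weight, space)
  sum(p$w * p$sw * (p$f - p$g)^2) / p$N
}

#' Gauss-Newton gradient and Hessian of the MSE cost
#'
#' Assembles the exact gradient and the Gauss-Newton Hessian of
#' [mse_cost()] with respect to the warp coefficients.  The Hessian entries
#' couple only splines with overlapping support, and the symmetrisation
#' weight is held fixed at the current warp (it is a cost weighting, not an
#' optimised quantity).
#'
#' @inheritParams mse_cost
#' @return list with `cost`, `grad` (length `3M`) and `H` (sparse symmetric
#'   positive semidefinite `3M x 3M` Gauss-Newton Hessian, including the
#'   factor 2 from differentiating the square).
#' @export
mse_grad_hess <- function(f, g, warp, ref_mask = NULL, mov_mask = NULL,
                          sym_weight = NULL, space = NULL) {
  p <- .mse_parts(f, g, warp, ref_mask, mov_mask, sym_weight, space,
                  gradient = TRUE)
  sqw <- sqrt(p$w * p$sw / p$N)
  resid <- matrix(sqw * (p$f - p$g), ncol = 1)
  terms <- cbind(0L, 0:2, 0L, 0L, 0L)
  fields <- -sqw * p$ggrad              # d resid / d w_(m,d) = -sqw g_d b_m
  act <- p$w > 0
  asm <- .gn_assemble(warp$grid, p$vox, terms, fields, resid, act)
  list(cost = sum(resid^2), grad = 2 * asm$grad, H = 2 * asm$H)
}
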