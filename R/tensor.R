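## Tensor image cost: masked, symmetrisation-weighted mean squared
## Frobenius norm between the finite-strain-reoriented reference tensors and
## the displaced moving tensors, with Gauss-Newton derivatives that include
## the rotational effect of the warp.
##
## Tensor rows follow the 6-component upper-triangle layout
## (xx, xy, xz, yy, yz, zz); the squared Frobenius norm over all 9 elements
## therefore uses element multiplicities (1, 2, 2, 1, 2, 1).

.tensor_mult <- c(1, 2, 2, 1, 2, 1)

#' Finite-strain rotation of a local Jacobian
#'
#' Extracts the rotational component \eqn{R = (JJ^\top)^{-1/2} J} of a local
#' Jacobian (the polar decomposition's orthogonal factor), used to reorient
#' tensors under the warp.
#'
#' @param J a 3x3 matrix, or an `N x 9` matrix of row-wise column-major
#'   Jacobians.
#' @return rotation(s) in the same shape as the input; every returned matrix
#'   is orthogonal with determinant +1.  Errors on singular or reflecting
#'   Jacobians (`det J <= 0`).
#' @export
finite_strain_rotation <- function(J) {
  if (is.matrix(J) && all(dim(J) == c(3, 3))) {
    return(matrix(cpp_polar_rotations(matrix(as.numeric(J), 1, 9)), 3, 3))
  }
  stopifnot(is.matrix(J), ncol(J) == 9)
  cpp_polar_rotations(J)
}

## Conjugate row-wise tensors by row-wise rotations: out = R D R^T
## (or R^T D R with `transpose = TRUE`).
## Rm: N x 9 (column-major rotations); D6: N x 6.
.conj_tensors <- function(Rm, D6, transpose = FALSE) {
  Dm <- cbind(D6[, 1], D6[, 2], D6[, 3],
              D6[, 2], D6[, 4], D6[, 5],
              D6[, 3], D6[, 5], D6[, 6])   # row-major full 3x3
  el <- function(i, j) Dm[, (i - 1) * 3 + j]
  Rl <- if (transpose) function(i, j) Rm[, j + 3 * (i - 1)] else
    function(i, j) Rm[, i + 3 * (j - 1)]
  A <- matrix(0, nrow(D6), 9)              # A = R D, row-major
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:3) s <- s + Rl(i, k) * el(k, j)
    A[, (i - 1) * 3 + j] <- s
  }
  out <- matrix(0, nrow(D6), 6)
  ut <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  for (q in 1:6) {
    i <- ut[q, 1]; j <- ut[q, 2]
    s <- 0
    for (k in 1:3) s <- s + A[, (i - 1) * 3 + k] * Rl(j, k)
    out[, q] <- s
  }
  out
}

## Linear component-wise sampling of a tensor volume at world points.
## Returns values (N x 6), optional per-component world gradients
## (N x 6 x 3), and the inside flag.
.sample_tensor <- function(tv, world, space, gradient = FALSE) {
  A <- world_to_imgvox(tv, space)
  vox <- xform_pts(A, world)
  n6 <- dim(tv$data)[4]
  N <- nrow(world)
  val <- matrix(0, N, 6)
  gr <- if (gradient) array(0, c(N, 6, 3)) else NULL
  inside <- NULL
  B <- A[1:3, 1:3]
  for (k in 1:6) {
    s <- trilinear_sample(tv$data[, , , k], vox, grad = gradient)
    val[, k] <- s$value
    if (gradient) for (cc in 1:3) {
      gr[, k, cc] <- s$grad[, 1] * B[1, cc] + s$grad[, 2] * B[2, cc] +
        s$grad[, 3] * B[3, cc]
    }
    if (is.null(inside)) inside <- s$inside
  }
  list(value = val, grad = gr, inside = inside)
}

## Shared evaluation core for the tensor cost.
.msfn_parts <- function(Fr, G, warp, ref_mask, mov_mask, sym_weight, space,
                        gradient = FALSE) {
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  world0 <- xform_pts(base$affine, vox)
  phi <- apply_warp(warp, vox)
  Fs <- .sample_tensor(Fr, world0, base)
  Gs <- .sample_tensor(G, phi, base, gradient = gradient)
  w <- .sample_weight(ref_mask, world0, base) *
    .sample_weight(mov_mask, phi, base)
  w[!Gs$inside] <- 0
  if (all(w == 0))
    stop("no overlap between the tensor volumes inside the warp domain")
  sw <- if (is.null(sym_weight)) sym_weight_at(warp, vox) else
    rep_len(sym_weight, nrow(vox))
  J <- warp_jacobian(warp, vox)
  list(vox = vox, w = w, sw = sw, Fv = Fs$value, Gv = Gs$value,
       Ggrad = Gs$grad, J = J, N = nrow(vox))
}

#' Mean squared Frobenius norm between tensor volumes under a warp
#'
#' The reference tensors are reoriented by the finite-strain rotation of the
#' local Jacobian (\eqn{R F R^\top}); the moving tensors are interpolated
#' component-wise at the warped positions.  The cost is the masked,
#' symmetrisation-weighted mean over the domain of the squared Frobenius
#' norm of the difference over all nine tensor elements (equivalently, the
#' sum of the per-element mean squared errors).  No intensity rescaling or
#' bias field applies to tensors.
#'
#' @param Fr,G reference and moving [tensor_volume()] objects.
#' @inheritParams mse_cost
#' @return scalar cost value.
#' @export
msfn_cost <- function(Fr, G, warp, ref_mask = NULL, mov_mask = NULL,
                      sym_weight = NULL, space = NULL) {
  p <- .msfn_parts(Fr, G, warp, ref_mask, mov_mask, sym_weight, space)
  Rm <- cpp_polar_rotations(p$J)
  RF <- .conj_tensors(Rm, p$Fv)
  d2 <- (RF - p$Gv)^2 %*% .tensor_mult
  sum(p$w * p$sw * d2) / p$N
}

#' Gauss-Newton gradient and Hessian of the tensor cost
#'
#' The derivatives include both the displacement effect on the moving
#' tensors and the rotational effect on the reference tensors (through the
#' closed-form derivative of the polar rotation factor with respect to the
#' local Jacobian).  Setting `rotation_term = FALSE` drops the rotational
#' contribution (useful for ablation; the cost itself is unchanged).
#'
#' @inheritParams msfn_cost
#' @param rotation_term include the derivative of the finite-strain
#'   rotation (default `TRUE`).
#' @return list with `cost`, `grad` and sparse GN `H` as in
#'   [mse_grad_hess()].
#' @export
msfn_grad_hess <- function(Fr, G, warp, ref_mask = NULL, mov_mask = NULL,
                           sym_weight = NULL, space = NULL,
                           rotation_term = TRUE) {
  p <- .msfn_parts(Fr, G, warp, ref_mask, mov_mask, sym_weight, space,
                   gradient = TRUE)
  rt <- cpp_rotation_terms(p$J, p$Fv)
  RF <- rt$RFRt
  sqw <- sqrt(p$w * p$sw / p$N)
  sqc <- sqrt(.tensor_mult)
  resid <- (RF - p$Gv) * (sqw %o% sqc)
  grid <- warp$grid
  Ainv <- solve(grid$space$affine[1:3, 1:3])
  h <- grid$spacing_vox
  ## term layout: for each element k (0..5) and direction d (0..2):
  ##   one value term (moving displacement) and three per-axis derivative
  ##   terms (reference rotation)
  terms <- NULL
  fields <- NULL
  for (k in 0:5) {
    for (d in 0:2) {
      terms <- rbind(terms, c(k, d, 0L, 0L, 0L))
      fields <- cbind(fields, -sqw * sqc[k + 1] * p$Ggrad[, k + 1, d + 1])
      if (rotation_term) {
        for (ax in 0:2) {
          dv <- c(0L, 0L, 0L)
          dv[ax + 1] <- 1L
          terms <- rbind(terms, c(k, d, dv))
          ## dJ_{d,a}/dw_{m,d} = db_m/dworld_a; chain to per-axis knot units
          Tt <- rowSums(vapply(1:3, function(a)
            rt$T[, k + 1 + 6 * d + 18 * (a - 1)] * Ainv[ax + 1, a],
            numeric(nrow(p$vox)))) / h[ax + 1]
          fields <- cbind(fields, sqw * sqc[k + 1] * Tt)
        }
      }
    }
  }
  act <- p$w > 0
  asm <- .gn_assemble(grid, p$vox, terms, fields, resid, act)
  list(cost = sum(resid^2), grad = 2 * asm$grad, H = 2 * asm$H)
}

#' Resample a tensor volume through a warp
#'
#' Produces the moving tensor volume in warp space: each component is
#' interpolated at the warped position and the interpolated tensor is then
#' reoriented by the finite-strain rotation of the local Jacobian, which
#' preserves the eigenvalues exactly.
#'
#' @param G a [tensor_volume()].
#' @param warp a [warp_field()]; must be diffeomorphic over the sampled
#'   domain (positive Jacobian determinant everywhere).
#' @param space optional output [warp_space()] (defaults to the warp's).
#' @return a [tensor_volume()] in warp space; voxels mapping outside the
#'   source volume are zero.
#' @details The reorientation applied is the inverse finite-strain rotation
#'   (conjugation by \eqn{R^\top}): since the registration cost matches
#'   \eqn{R F R^\top} against \eqn{G(\phi(x))}, rotating the interpolated
#'   moving tensors back by \eqn{R^\top} makes a perfectly registered
#'   moving volume reproduce the reference tensors.
#' @export
resample_tensors <- function(G, warp, space = NULL) {
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  phi <- apply_warp(warp, vox)
  Gs <- .sample_tensor(G, phi, base)
  J <- warp_jacobian(warp, vox)
  if (any(.det3(J) <= 0))
    stop("warp is not diffeomorphic over the sampled domain")
  Rm <- cpp_polar_rotations(J)
  out <- .conj_tensors(Rm, Gs$value, transpose = TRUE)
  out[!Gs$inside, ] <- 0
  tensor_volume(array(out, c(space$shape, 6)), space$voxel_size,
                space$affine)
}
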