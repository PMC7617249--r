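## Warp regularisation: the mean (over the sampling grid) of the sum of the
## squared logarithms of the singular values of the local Jacobian.  The
## penalty is zero exactly for locally rigid transformations, diverges as
## any singular value approaches zero or infinity (so accepted warps remain
## diffeomorphic), and penalises expansion and compression symmetrically.

## Shared sampling for the penalty.  Returns NULL sw/J when the warp folds.
.reg_parts <- function(warp, space, sym_weight) {
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  J <- warp_jacobian(warp, vox)
  sw <- if (is.null(sym_weight)) 1 + abs(.det3(J)) else
    rep_len(sym_weight, nrow(vox))
  list(vox = vox, J = J, sw = sw, N = nrow(vox))
}

#' Squared-log-singular-value penalty of a warp
#'
#' \deqn{C_r = \frac{1}{N}\sum_x \omega(x) \sum_{i=1}^3 (\log s_i(J(x)))^2}
#' where \eqn{s_i} are the singular values of the local Jacobian.  Returns
#' `Inf` when the warp folds (any non-positive Jacobian determinant), which
#' the optimiser treats as a rejected step.
#'
#' @param warp a [warp_field()].
#' @param space optional sampling [warp_space()] (defaults to the warp's
#'   voxel grid).
#' @param sym_weight `NULL` for the `1 + |J|` weighting, or a numeric
#'   factor / per-sample vector (use `1` to disable).
#' @return scalar penalty (`Inf` if folded).
#' @export
reg_cost <- function(warp, space = NULL, sym_weight = NULL) {
  p <- .reg_parts(warp, space, sym_weight)
  if (any(.det3(p$J) <= 0)) return(Inf)
  s <- cpp_singular_values(p$J)
  sum(p$sw * rowSums(log(s)^2)) / p$N
}

#' Gauss-Newton gradient and Hessian of the warp penalty
#'
#' Treats the three per-sample residuals \eqn{\sqrt{\omega/N}\,\log s_i} as a
#' least-squares problem; the derivative of each \eqn{\log s_i} with respect
#' to the local Jacobian follows from the singular value decomposition
#' (\eqn{u_i v_i^\top / s_i}) and is chained through the closed-form
#' B-spline derivatives.
#'
#' @inheritParams reg_cost
#' @return list with `cost`, `grad` and sparse GN `H` as in
#'   [mse_grad_hess()].  Errors if the warp folds anywhere on the grid.
#' @export
reg_grad_hess <- function(warp, space = NULL, sym_weight = NULL) {
  p <- .reg_parts(warp, space, sym_weight)
  lt <- cpp_logsv_terms(p$J)
  if (!lt$ok) stop("warp folds on the sampling grid; penalty is infinite")
  sqw <- sqrt(p$sw / p$N)
  resid <- lt$logs * sqw
  grid <- warp$grid
  Ainv <- solve(grid$space$affine[1:3, 1:3])
  h <- grid$spacing_vox
  terms <- NULL
  fields <- NULL
  for (k in 0:2) {                       # residual index (singular value)
    for (d in 0:2) {                     # coefficient direction
      for (ax in 0:2) {                  # per-axis spline derivative
        dv <- c(0L, 0L, 0L)
        dv[ax + 1] <- 1L
        terms <- rbind(terms, c(k, d, dv))
        Pt <- rowSums(vapply(1:3, function(a)
          lt$P[, k + 1 + 3 * d + 9 * (a - 1)] * Ainv[ax + 1, a],
          numeric(p$N))) / h[ax + 1]
        fields <- cbind(fields, sqw * Pt)
      }
    }
  }
  asm <- .gn_assemble(grid, p$vox, terms, fields, resid,
                      rep(TRUE, p$N))
  list(cost = sum(resid^2), grad = 2 * asm$grad, H = 2 * asm$H)
}

#' Check that a warp is diffeomorphic
#'
#' Samples the Jacobian determinant on the warp-space voxel grid and reports
#' the minimum and the fraction of non-positive samples.  A B-spline warp is
#' smooth by construction, so a positive determinant everywhere makes it
#' diffeomorphic.
#'
#' @inheritParams reg_cost
#' @return list with `min_det` and `frac_nonpos`.
#' @export
check_diffeomorphic <- function(warp, space = NULL) {
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  dets <- .det3(warp_jacobian(warp, vox))
  list(min_det = min(dets), frac_nonpos = mean(dets <= 0))
}
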