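## Multiplicative bias field on the reference image.
##
## MRI transmit/receive inhomogeneities appear as a smooth multiplicative
## intensity modulation that a global rescaling cannot remove.  The field is
## modelled as exp(s(x)) with s a cubic-B-spline scalar field on its own
## (coarse) knot grid -- the log parametrisation guarantees positivity.  It
## is estimated with the warp held fixed, by Gauss-Newton minimisation of
## bending-energy-penalised MSE, and is interleaved with warp updates.

#' Construct a bias-field model
#'
#' @param space the [warp_space()] the field lives on.
#' @param spacing_mm knot spacing of the field's own B-spline grid
#'   (typically much coarser than the warp's).
#' @param coeffs optional coefficient vector (log-field spline weights);
#'   defaults to zero, i.e. a unit field.
#' @param bending_weight nonnegative weight of the bending-energy smoothness
#'   penalty used when fitting.
#' @return an object of class `bias_field`.
#' @export
bias_field <- function(space, spacing_mm, coeffs = NULL, bending_weight = 1) {
  grid <- knot_grid(space, spacing_mm)
  if (is.null(coeffs)) coeffs <- numeric(grid$M)
  stopifnot(length(coeffs) == grid$M, all(is.finite(coeffs)),
            bending_weight >= 0)
  structure(list(grid = grid, coeffs = as.numeric(coeffs),
                 bending_weight = bending_weight),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  cat("<bias_field> ", paste(x$grid$counts, collapse = " x "),
      " splines, knot spacing ",
      paste(signif(x$grid$spacing_mm, 4), collapse = " x "),
      " mm, bending weight ", x$bending_weight, "\n", sep = "")
  invisible(x)
}

#' Evaluate a bias field
#'
#' @param model a [bias_field()].
#' @param vox `N x 3` matrix of 0-based warp-space voxel coordinates.
#' @return numeric vector of strictly positive multiplicative factors
#'   (`exp` of the spline sum; all-zero coefficients give 1 everywhere).
#' @export
evaluate_bias <- function(model, vox) {
  axw <- warp_axis_weights(model$grid, vox)
  exp(.bs_eval3(array(model$coeffs, model$grid$counts), axw))
}

## Bending-energy residual setup: per-sample second partial derivatives of
## the log-field in mm^-2, as 6 unique (a, b) combinations with
## multiplicities (1, 2, 2, 1, 2, 1).  Returns terms/fields for the engine
## plus a function evaluating the residual matrix for given coefficients.
.bending_terms <- function(grid, nsamp, weight) {
  h_mm <- grid$spacing_mm
  combos <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  mult <- c(1, 2, 2, 1, 2, 1)
  terms <- NULL
  fields <- NULL
  for (q in 1:6) {
    a <- combos[q, 1]; b <- combos[q, 2]
    dv <- c(0L, 0L, 0L)
    dv[a] <- dv[a] + 1L
    dv[b] <- dv[b] + 1L
    terms <- rbind(terms, c(q - 1L, 0L, dv))
    fields <- cbind(fields,
                    rep(sqrt(weight * mult[q] / nsamp) / (h_mm[a] * h_mm[b]),
                        nsamp))
  }
  list(terms = terms, fields = fields, combos = combos, mult = mult)
}

## Second partial derivatives of the log bias field at sample points
## (N x 6, mm^-2, combos as in .bending_terms).
.bias_second_derivs <- function(model, vox) {
  grid <- model$grid
  carr <- array(model$coeffs, grid$counts)
  h_mm <- grid$spacing_mm
  combos <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3))
  out <- matrix(0, nrow(vox), 6)
  for (q in 1:6) {
    dv <- c(0L, 0L, 0L)
    dv[combos[q, 1]] <- dv[combos[q, 1]] + 1L
    dv[combos[q, 2]] <- dv[combos[q, 2]] + 1L
    axw <- warp_axis_weights(grid, vox, deriv = dv)
    out[, q] <- .bs_eval3(carr, axw) / (h_mm[combos[q, 1]] * h_mm[combos[q, 2]])
  }
  out
}

## Joint bias objective: MSE(bias * f, g(phi)) + bending_weight * bending.
.bias_objective <- function(model, fval, gval, w, vox) {
  b <- evaluate_bias(model, vox)
  mse <- sum(w * (b * fval - gval)^2) / length(fval)
  d2 <- .bias_second_derivs(model, vox)
  bend <- sum((d2^2) %*% c(1, 2, 2, 1, 2, 1)) / length(fval)
  mse + model$bending_weight * bend
}

#' Fit the bias field with the warp held fixed
#'
#' Gauss-Newton minimisation of the bending-energy-penalised MSE between the
#' bias-modulated reference image and the warped moving image.  The warp is
#' not updated here; interleaving with warp updates is handled by the
#' registration driver.
#'
#' @param f,g reference and moving [image3d()] (already intensity-scaled).
#' @param warp the fixed [warp_field()].
#' @param model the current [bias_field()].
#' @param ref_mask,mov_mask optional weight volumes as in [mse_cost()].
#' @param space optional sampling [warp_space()].
#' @param max_iter,tol Gauss-Newton iteration controls.
#' @return the updated [bias_field()], with attribute `"objective"` holding
#'   the (non-increasing) objective trace.
#' @export
fit_bias <- function(f, g, warp, model, ref_mask = NULL, mov_mask = NULL,
                     space = NULL, max_iter = 10L, tol = 1e-6) {
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  world0 <- xform_pts(base$affine, vox)
  phi <- apply_warp(warp, vox)
  fs <- .sample_scalar(f, world0, base)
  gs <- .sample_scalar(g, phi, base)
  w <- .sample_weight(ref_mask, world0, base) *
    .sample_weight(mov_mask, phi, base)
  w[!gs$inside] <- 0
  N <- nrow(vox)
  bt <- .bending_terms(model$grid, N, model$bending_weight)
  obj <- .bias_objective(model, fs$value, gs$value, w, vox)
  if (!is.finite(obj)) stop("non-finite bias objective at start")
  trace <- obj
  mu <- 1e-6
  for (it in seq_len(max_iter)) {
    b <- evaluate_bias(model, vox)
    sqw <- sqrt(w / N)
    r_img <- matrix(sqw * (b * fs$value - gs$value), ncol = 1)
    f_img <- matrix(sqw * b * fs$value, ncol = 1)     # d resid / d c_m = b f b_m
    tb <- bt$terms
    tb[, 1] <- tb[, 1] + 1L                 # bending residuals follow the image one
    terms <- rbind(c(0L, 0L, 0L, 0L, 0L), tb)
    d2 <- .bias_second_derivs(model, vox)
    r_bend <- d2 * rep(sqrt(model$bending_weight * bt$mult / N),
                       each = N)
    resid <- cbind(r_img, r_bend)
    fields <- cbind(f_img, bt$fields)
    asm <- .gn_assemble(model$grid, vox, terms, fields, resid,
                        rep(TRUE, N), ndir = 1L)
    H <- asm$H + mu * Matrix::Diagonal(model$grid$M, pmax(Matrix::diag(asm$H), 1e-12))
    step <- as.numeric(Matrix::solve(Matrix::forceSymmetric(H), -asm$grad))
    cand <- model
    cand$coeffs <- model$coeffs + step
    obj_new <- .bias_objective(cand, fs$value, gs$value, w, vox)
    if (!is.finite(obj_new)) stop("non-finite bias objective during fit")
    if (obj_new < obj) {
      rel <- (obj - obj_new) / max(obj, .Machine$double.eps)
      model <- cand
      obj <- obj_new
      trace <- c(trace, obj)
      mu <- mu / 10
      if (rel < tol) break
    } else {
      mu <- max(mu, 1e-6) * 100
      if (mu > 1e8) break
    }
  }
  attr(model, "objective") <- trace
  model
}
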