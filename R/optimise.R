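## Gauss-Newton / Levenberg-Marquardt estimation of the warp over a
## coarse-to-fine pyramid.
##
## Each pyramid level fixes a warp knot spacing, an image smoothing FWHM and
## a cost-sampling step chosen so that the smoothed images are alias-free on
## the subsampled grid.  Within a level, damped Gauss-Newton steps are
## solved by Jacobi-preconditioned conjugate gradients on the sparse Hessian
## of the total cost; steps are accepted only when the true total cost
## decreases, so the accepted cost sequence is strictly decreasing and every
## returned warp has positive Jacobian determinant (the penalty is infinite
## otherwise).

#' Default multiresolution schedule
#'
#' Levels run coarse-to-fine at knot spacings 16, 8, 4, 2, 1 mm down to the
#' requested final resolution.  Smoothing is a quarter of the warp
#' resolution (4 mm FWHM at 16 mm knots), and the regularisation weight is
#' 0.18 at 1 mm warp resolution, divided by 0.85 for each doubling of the
#' knot spacing (0.21 at 2 mm, 0.25 at 4 mm, ...), reported rounded to two
#' decimals.  Image terms default to weight 1.
#'
#' @param final_res finest warp knot spacing in mm.
#' @return a data frame of class `pyramid_schedule` with columns
#'   `knot_mm`, `fwhm_mm`, `subsample_mm`, `lambda_reg`.
#' @export
default_schedule <- function(final_res = 1) {
  stopifnot(final_res > 0)
  knots <- 16 / 2^(0:10)
  knots <- knots[knots >= final_res - 1e-9]
  if (length(knots) == 0 || knots[length(knots)] > final_res)
    knots <- c(knots, final_res)
  fwhm <- knots / 4
  lam <- round(0.18 / 0.85^log2(knots), 2)
  out <- data.frame(knot_mm = knots, fwhm_mm = fwhm,
                    subsample_mm = mapply(subsample_for, fwhm, knots),
                    lambda_reg = lam)
  class(out) <- c("pyramid_schedule", "data.frame")
  out
}

#' Nyquist-safe subsampling step for a pyramid level
#'
#' Treats the Gaussian smoothing kernel as a low-pass filter: a kernel of
#' full width `fwhm` suppresses content above roughly `1/fwhm` cycles/mm, so
#' a sampling step of `fwhm / 2` keeps the smoothed image alias-free.  The
#' step is clamped to lie between a quarter of and exactly the warp knot
#' spacing.
#'
#' @param fwhm smoothing kernel FWHM in mm (0 for none).
#' @param knot warp knot spacing in mm.
#' @return sampling step in mm.
#' @export
subsample_for <- function(fwhm, knot) {
  stopifnot(fwhm >= 0, knot > 0)
  desired <- if (fwhm <= 0) 0 else fwhm / 2
  min(max(desired, knot / 4), knot)
}

#' Optimiser control parameters
#'
#' @param max_iter maximum damped Gauss-Newton steps per level.
#' @param tol relative total-cost decrease below which (over two consecutive
#'   accepted steps) a level is converged.
#' @param mu0_factor initial Levenberg-Marquardt damping as a fraction of
#'   the mean Hessian diagonal.
#' @param cg_tol,cg_maxit conjugate-gradient solver controls.
#' @param outer_iter warp/bias interleaving rounds per level when the bias
#'   field is enabled.
#' @return list of control values.
#' @export
mmreg_control <- function(max_iter = 20L, tol = 1e-4, mu0_factor = 1e-3,
                          cg_tol = 1e-6, cg_maxit = 500L, outer_iter = 3L) {
  list(max_iter = as.integer(max_iter), tol = tol, mu0_factor = mu0_factor,
       cg_tol = cg_tol, cg_maxit = as.integer(cg_maxit),
       outer_iter = as.integer(outer_iter))
}

## Jacobi-preconditioned conjugate gradients for sparse SPD systems.
.pcg <- function(H, b, tol = 1e-6, maxit = 500L) {
  dg <- Matrix::diag(H)
  Minv <- 1 / pmax(dg, max(dg) * 1e-12 + 1e-300)
  x <- numeric(length(b))
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = x, ok = TRUE, iter = 0L))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Hp <- as.numeric(H %*% p)
    pHp <- sum(p * Hp)
    if (pHp <= 0) return(list(x = x, ok = FALSE, iter = it))
    alpha <- rz / pHp
    x <- x + alpha * p
    r <- r - alpha * Hp
    if (sqrt(sum(r^2)) < tol * nb) return(list(x = x, ok = TRUE, iter = it))
    z <- Minv * r
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  list(x = x, ok = FALSE, iter = maxit)
}

## Smooth the scalar/tensor data of an image-like object on its own grid.
.smooth_img <- function(img, fwhm) {
  if (is.null(img) || fwhm <= 0) return(img)
  out <- img
  if (inherits(img, "tensor_volume")) {
    for (k in 1:6)
      out$data[, , , k] <- gauss_smooth(img$data[, , , k], fwhm, img$voxel_size)
  } else {
    out$data <- gauss_smooth(img$data, fwhm, img$voxel_size)
  }
  out
}

## Total cost at a warp for the current level inputs (sym weight recomputed
## from the candidate warp itself -- this is the true objective).
.total_cost <- function(w, lv) {
  sw <- if (lv$sym) NULL else 1
  Cs <- Ct <- 0
  if (!is.null(lv$f))
    Cs <- mse_cost(lv$f, lv$g, w, lv$ref_mask, lv$mov_mask, sw, lv$space)
  if (!is.null(lv$Fr))
    Ct <- msfn_cost(lv$Fr, lv$G, w, lv$ref_mask_t, lv$mov_mask_t, sw, lv$space)
  Cr <- reg_cost(w, lv$space, sw)
  c(Cs = Cs, Ct = Ct, Cr = Cr,
    total = lv$lambda_s * Cs + lv$lambda_t * Ct + lv$lambda_r * Cr)
}

## Assemble the total gradient and Hessian with the symmetrisation weight
## frozen at the current warp.
.total_grad_hess <- function(w, lv) {
  vox <- vox_in_base(lv$space, w$grid$space)
  sw <- if (lv$sym) sym_weight_at(w, vox) else rep(1, nrow(vox))
  grad <- numeric(3 * w$grid$M)
  H <- NULL
  addH <- function(H, A, s) if (is.null(H)) s * A else H + s * A
  if (!is.null(lv$f)) {
    gs <- mse_grad_hess(lv$f, lv$g, w, lv$ref_mask, lv$mov_mask, sw, lv$space)
    grad <- grad + lv$lambda_s * gs$grad
    H <- addH(H, gs$H, lv$lambda_s)
  }
  if (!is.null(lv$Fr)) {
    gt <- msfn_grad_hess(lv$Fr, lv$G, w, lv$ref_mask_t, lv$mov_mask_t, sw,
                         lv$space)
    grad <- grad + lv$lambda_t * gt$grad
    H <- addH(H, gt$H, lv$lambda_t)
  }
  gr <- reg_grad_hess(w, lv$space, sw)
  grad <- grad + lv$lambda_r * gr$grad
  H <- addH(H, gr$H, lv$lambda_r)
  list(grad = grad, H = H)
}

## One level of damped Gauss-Newton. Returns warp + iteration records.
.lm_level <- function(w, lv, control, level_id, log_con = NULL) {
  rec <- list()
  cost <- .total_cost(w, lv)
  small_steps <- 0L
  mu <- NA_real_
  for (it in seq_len(control$max_iter)) {
    gh <- .total_grad_hess(w, lv)
    dg <- Matrix::diag(gh$H)
    mdg <- mean(dg)
    if (is.na(mu)) mu <- control$mu0_factor * mdg
    accepted <- FALSE
    for (try in 1:8) {
      Hd <- gh$H + Matrix::Diagonal(length(dg), mu * pmax(dg, 1e-12 * mdg))
      sol <- .pcg(Hd, -gh$grad, tol = control$cg_tol, maxit = control$cg_maxit)
      if (sol$ok) {
        cand <- w
        cand$coeffs <- w$coeffs + matrix(sol$x, 3, w$grid$M, byrow = TRUE)
        cost_new <- .total_cost(cand, lv)
        if (is.finite(cost_new["total"]) && cost_new["total"] < cost["total"]) {
          rel <- (cost["total"] - cost_new["total"]) / max(cost["total"], 1e-300)
          w <- cand
          cost <- cost_new
          mu <- mu / 10
          accepted <- TRUE
          small_steps <- if (rel < control$tol) small_steps + 1L else 0L
          break
        }
      }
      mu <- max(mu * 10, 1e-12 * mdg)
      if (mu > 1e10 * max(mdg, 1e-300)) break
    }
    rec[[length(rec) + 1]] <- data.frame(
      level = level_id, iter = it, Cs = cost["Cs"], Ct = cost["Ct"],
      Cr = cost["Cr"], total = cost["total"], accepted = accepted, mu = mu,
      row.names = NULL)
    if (!is.null(log_con)) {
      writeLines(jsonlite::toJSON(list(level = level_id, iter = it,
                                       Cs = unname(cost["Cs"]),
                                       Ct = unname(cost["Ct"]),
                                       Cr = unname(cost["Cr"]),
                                       total = unname(cost["total"]),
                                       accepted = accepted),
                                  auto_unbox = TRUE, digits = NA), log_con)
    }
    if (!accepted || small_steps >= 2L) break
  }
  list(warp = w, trace = do.call(rbind, rec), cost = cost)
}

#' Multimodal nonlinear registration
#'
#' Estimates a cubic-B-spline warp that maps the reference space onto the
#' moving subject by minimising a weighted sum of a scalar MSE cost, a
#' tensor mean-squared-Frobenius cost with finite-strain reorientation, and
#' the squared-log-singular-value penalty, over a coarse-to-fine pyramid.
#' All optimisation is damped Gauss-Newton on the sparse Hessian; steps are
#' accepted only if the total cost decreases, and the returned warp is
#' diffeomorphic over the sampled domain.  The procedure is deterministic:
#' identical inputs give identical warps.
#'
#' @param ref_scalar,mov_scalar reference and moving [image3d()] (optional
#'   if tensors are given).  Intensities are robustly rescaled unless
#'   `scale_intensities = FALSE`.
#' @param ref_tensor,mov_tensor optional [tensor_volume()] pair.
#' @param ref_mask,mov_mask optional nonnegative weight volumes applied to
#'   all image terms.
#' @param space the [warp_space()] defining the estimation domain; defaults
#'   to the grid of the reference scalar (or tensor) image.
#' @param schedule a [default_schedule()]-style data frame.
#' @param lambda_scalar,lambda_tensor weights of the image cost terms.
#' @param reg_scale global multiplier on the schedule's per-level
#'   regularisation weight.
#' @param bias estimate a multiplicative bias field on the reference scalar
#'   image (interleaved with warp updates).
#' @param bias_spacing knot spacing of the bias field in mm (default: 8x
#'   the finest warp knot spacing).
#' @param bias_bending bending-energy weight of the bias field.
#' @param sym_weight use the inverse-consistency weighting `1 + |J|` on all
#'   cost terms (default `TRUE`).
#' @param init optional initial [warp_field()].
#' @param control a [mmreg_control()] list.
#' @param log_file optional path; per-iteration cost components are appended
#'   as JSON lines.
#' @param verbose print per-level progress.
#' @return an object of class `mmreg_fit`; see [coef.mmreg_fit()],
#'   [predict.mmreg_fit()], [summary.mmreg_fit()].
#' @export
mmreg <- function(ref_scalar = NULL, mov_scalar = NULL,
                  ref_tensor = NULL, mov_tensor = NULL,
                  ref_mask = NULL, mov_mask = NULL, space = NULL,
                  schedule = default_schedule(4),
                  lambda_scalar = 1, lambda_tensor = 1, reg_scale = 1,
                  bias = FALSE, bias_spacing = NULL, bias_bending = 1e-3,
                  sym_weight = TRUE, scale_intensities = TRUE, init = NULL,
                  control = mmreg_control(), log_file = NULL,
                  verbose = FALSE) {
  cl <- match.call()
  has_scalar <- !is.null(ref_scalar)
  has_tensor <- !is.null(ref_tensor)
  if (!has_scalar && !has_tensor)
    stop("at least one image pair (scalar or tensor) is required")
  if (has_scalar && is.null(mov_scalar))
    stop("mov_scalar is required with ref_scalar")
  if (has_tensor && is.null(mov_tensor))
    stop("mov_tensor is required with ref_tensor")
  if (bias && !has_scalar)
    stop("bias-field estimation applies to the reference scalar image only; ",
         "it is not available for tensor-only registration")
  if (is.null(space))
    space <- space_of(if (has_scalar) ref_scalar else ref_tensor)
  if (bias && !all(dim(ref_scalar$data) == space$shape))
    stop("bias-field estimation requires the reference scalar image to be ",
         "defined on the warp space grid")
  ## global robust intensity scaling (scalar pair only; tensors are
  ## quantitative and never rescaled); originals are kept for the
  ## predict/residuals methods
  orig <- list(ref_scalar = ref_scalar, mov_scalar = mov_scalar,
               ref_tensor = ref_tensor, mov_tensor = mov_tensor,
               ref_mask = ref_mask, mov_mask = mov_mask)
  scales <- c(ref = 1, mov = 1)
  if (has_scalar && scale_intensities) {
    scales <- c(ref = robust_scale(ref_scalar, ref_mask),
                mov = robust_scale(mov_scalar, mov_mask))
    ref_scalar$data <- ref_scalar$data * scales["ref"]
    mov_scalar$data <- mov_scalar$data * scales["mov"]
  }
  log_con <- NULL
  if (!is.null(log_file)) {
    log_con <- file(log_file, open = "a")
    on.exit(close(log_con), add = TRUE)
  }
  warp <- init
  bias_model <- NULL
  if (bias) {
    if (is.null(bias_spacing))
      bias_spacing <- 8 * min(schedule$knot_mm)
    bias_model <- bias_field(space, bias_spacing, bending_weight = bias_bending)
  }
  traces <- list()
  level_warps <- list()
  for (l in seq_len(nrow(schedule))) {
    knot <- schedule$knot_mm[l]
    fwhm <- schedule$fwhm_mm[l]
    step <- schedule$subsample_mm[l]
    grid <- knot_grid(space, knot)
    lspace <- subsample_space(space, step)
    ## carry the warp to this level's grid
    if (is.null(warp)) {
      warp <- warp_field(grid)
    } else {
      vox <- vox_in_base(lspace, space)
      warp <- fit_warp_to_displacement(grid, vox, warp_displacement(warp, vox))
      ## the least-squares projection can overshoot near the margins; pull
      ## a folded start back toward the identity until it is feasible
      shrink <- 0
      while (!is.finite(reg_cost(warp, lspace, 1)) && shrink < 40) {
        warp$coeffs <- warp$coeffs * 0.9
        shrink <- shrink + 1
      }
    }
    lv <- list(space = lspace, sym = sym_weight,
               lambda_s = if (has_scalar) lambda_scalar else 0,
               lambda_t = if (has_tensor) lambda_tensor else 0,
               lambda_r = reg_scale * schedule$lambda_reg[l],
               f = NULL, g = NULL, Fr = NULL, G = NULL,
               ref_mask = ref_mask, mov_mask = mov_mask,
               ref_mask_t = ref_mask, mov_mask_t = mov_mask)
    if (has_scalar) {
      f_s <- .smooth_img(ref_scalar, fwhm)
      if (!is.null(bias_model)) {
        bvol <- evaluate_bias(bias_model, space_grid(space))
        f_s$data <- f_s$data * array(bvol, dim(f_s$data))
      }
      lv$f <- f_s
      lv$g <- .smooth_img(mov_scalar, fwhm)
    }
    if (has_tensor) {
      lv$Fr <- .smooth_img(ref_tensor, fwhm)
      lv$G <- .smooth_img(mov_tensor, fwhm)
    }
    n_outer <- if (bias) control$outer_iter else 1L
    for (outer in seq_len(n_outer)) {
      res <- .lm_level(warp, lv, control, l, log_con)
      warp <- res$warp
      traces[[length(traces) + 1]] <- res$trace
      if (bias) {
        bias_model <- fit_bias(ref_scalar, .smooth_img(mov_scalar, fwhm),
                               warp, bias_model, ref_mask, mov_mask,
                               space = lspace)
        bvol <- evaluate_bias(bias_model, space_grid(space))
        f_s <- .smooth_img(ref_scalar, fwhm)
        f_s$data <- f_s$data * array(bvol, dim(f_s$data))
        lv$f <- f_s
      }
    }
    level_warps[[l]] <- warp
    if (verbose)
      message(sprintf("level %d (knot %.3g mm): total cost %.6g",
                      l, knot, res$cost["total"]))
  }
  trace <- do.call(rbind, traces)
  diffeo <- check_diffeomorphic(warp)
  structure(list(warp = warp, bias = bias_model, space = space,
                 schedule = schedule, trace = trace, diffeo = diffeo,
                 level_warps = level_warps,
                 lambda = c(scalar = if (has_scalar) lambda_scalar else 0,
                            tensor = if (has_tensor) lambda_tensor else 0),
                 sym_weight = sym_weight, scales = scales,
                 images = orig,
                 call = cl),
            class = "mmreg_fit")
}

#' Inverse-consistency error of a forward/backward warp pair
#'
#' Composes the forward and backward warps and reports statistics of
#' `||phi_bwd(phi_fwd(x)) - x||` in mm over the forward warp space.
#'
#' @param warp_fwd,warp_bwd forward and backward [warp_field()] objects.
#' @param mask optional [image3d()] weight volume; voxels with positive
#'   weight are included.
#' @return list with `mean_mm`, `max_mm` and `frac_excluded` (samples whose
#'   composition leaves the backward domain).
#' @export
ic_error <- function(warp_fwd, warp_bwd, mask = NULL) {
  spf <- warp_fwd$grid$space
  spb <- warp_bwd$grid$space
  vox <- space_grid(spf)
  keep <- rep(TRUE, nrow(vox))
  if (!is.null(mask)) {
    w <- .sample_weight(mask, xform_pts(spf$affine, vox), spf)
    keep <- w > 0
  }
  vox <- vox[keep, , drop = FALSE]
  world0 <- xform_pts(spf$affine, vox)
  y <- apply_warp(warp_fwd, vox)
  vb <- xform_pts(solve(spb$affine), y)
  nb <- spb$shape
  inside <- vb[, 1] >= 0 & vb[, 1] <= nb[1] - 1 &
    vb[, 2] >= 0 & vb[, 2] <= nb[2] - 1 &
    vb[, 3] >= 0 & vb[, 3] <= nb[3] - 1
  z <- apply_warp(warp_bwd, vb[inside, , drop = FALSE])
  err <- sqrt(rowSums((z - world0[inside, , drop = FALSE])^2))
  list(mean_mm = mean(err), max_mm = max(err),
       frac_excluded = 1 - mean(inside))
}

#' Resample a scalar image through a warp
#'
#' Evaluates `g(phi(x))` on the warp space by cubic-spline interpolation
#' (or nearest-neighbour for label volumes).
#'
#' @param img an [image3d()].
#' @param warp a [warp_field()].
#' @param space optional output [warp_space()].
#' @param method `"spline"` or `"nearest"`.
#' @return an [image3d()] in warp space (out-of-view voxels are zero).
#' @export
resample_image <- function(img, warp, space = NULL,
                           method = c("spline", "nearest")) {
  method <- match.arg(method)
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  phi <- apply_warp(warp, vox)
  iv <- xform_pts(world_to_imgvox(img, base), phi)
  if (method == "nearest") {
    val <- nearest_sample(img$data, iv)
    n <- dim(img$data)
    inside <- iv[, 1] >= -0.5 & iv[, 1] <= n[1] - 0.5 &
      iv[, 2] >= -0.5 & iv[, 2] <= n[2] - 0.5 &
      iv[, 3] >= -0.5 & iv[, 3] <= n[3] - 0.5
    val[!inside] <- 0
  } else {
    s <- spline_sample(spline_prep(img$data), iv)
    val <- s$value
    val[!s$inside] <- 0
  }
  image3d(array(val, space$shape), space$voxel_size, space$affine)
}

## ---- methods for the fit object -----------------------------------------

#' @export
print.mmreg_fit <- function(x, ...) {
  disp <- warp_to_volume(x$warp)
  cat("Multimodal B-spline registration fit\n")
  cat("  warp: ", paste(x$warp$grid$counts, collapse = " x "),
      " splines per direction at ",
      paste(signif(x$warp$grid$spacing_mm, 3), collapse = " x "),
      " mm knots\n", sep = "")
  cat(sprintf("  mean |displacement|: %.4g mm (max %.4g mm)\n",
              mean(sqrt(rowSums(matrix(disp, ncol = 3)^2))),
              max(abs(disp))))
  cat(sprintf("  final total cost: %.6g over %d accepted steps\n",
              utils::tail(x$trace$total, 1), sum(x$trace$accepted)))
  cat(sprintf("  min Jacobian determinant: %.4g (%.3g%% non-positive)\n",
              x$diffeo$min_det, 100 * x$diffeo$frac_nonpos))
  invisible(x)
}

#' Summary of a registration fit
#'
#' @param object an `mmreg_fit`.
#' @param ... unused.
#' @return a list with the per-level cost table, displacement statistics and
#'   the diffeomorphism check, printed compactly.
#' @export
summary.mmreg_fit <- function(object, ...) {
  disp <- matrix(warp_to_volume(object$warp), ncol = 3)
  mag <- sqrt(rowSums(disp^2))
  lev <- do.call(rbind, lapply(split(object$trace, object$trace$level),
                               function(d) d[nrow(d), ]))
  out <- list(levels = lev,
              displacement = c(mean = mean(mag), max = max(mag)),
              diffeo = object$diffeo, lambda = object$lambda)
  class(out) <- "summary.mmreg_fit"
  out
}

#' @export
print.summary.mmreg_fit <- function(x, ...) {
  cat("Per-level final costs:\n")
  print(x$levels[, c("level", "Cs", "Ct", "Cr", "total")], row.names = FALSE)
  cat(sprintf("Displacement: mean %.4g mm, max %.4g mm\n",
              x$displacement["mean"], x$displacement["max"]))
  cat(sprintf("Min |J| = %.4g; non-positive fraction = %.3g\n",
              x$diffeo$min_det, x$diffeo$frac_nonpos))
  invisible(x)
}

#' Warp coefficients of a fit
#'
#' @param object an `mmreg_fit`.
#' @param ... unused.
#' @return the `3 x M` matrix of B-spline displacement coefficients (mm).
#' @export
coef.mmreg_fit <- function(object, ...) object$warp$coeffs

#' Predict from a registration fit
#'
#' Transforms coordinates or resamples the moving image(s) into the
#' reference (warp) space.
#'
#' @param object an `mmreg_fit`.
#' @param newdata for `type = "coords"`, an `N x 3` matrix of 0-based
#'   warp-space voxel coordinates (default: the full warp-space grid); for
#'   the image types, an optional replacement image to resample.
#' @param type `"coords"` (warped world coordinates), `"image"` (moving
#'   scalar resampled into reference space) or `"tensor"` (moving tensors
#'   resampled with finite-strain reorientation).
#' @param ... unused.
#' @return per `type`: a coordinate matrix, an [image3d()], or a
#'   [tensor_volume()].
#' @export
predict.mmreg_fit <- function(object, newdata = NULL,
                              type = c("coords", "image", "tensor"), ...) {
  type <- match.arg(type)
  if (type == "coords") {
    if (is.null(newdata)) newdata <- space_grid(object$space)
    return(apply_warp(object$warp, newdata))
  }
  if (type == "image") {
    img <- if (is.null(newdata)) object$images$mov_scalar else newdata
    if (is.null(img)) stop("no moving scalar image in the fit")
    return(resample_image(img, object$warp))
  }
  tv <- if (is.null(newdata)) object$images$mov_tensor else newdata
  if (is.null(tv)) stop("no moving tensor volume in the fit")
  resample_tensors(tv, object$warp)
}

#' Intensity residuals of a registration fit
#'
#' @param object an `mmreg_fit`.
#' @param ... unused.
#' @return an [image3d()] of `f - g(phi)` on the warp space (after the
#'   fit's intensity scaling and bias field, if any).
#' @export
residuals.mmreg_fit <- function(object, ...) {
  if (is.null(object$images$ref_scalar))
    stop("residual volumes are defined for scalar registrations")
  f <- object$images$ref_scalar
  f$data <- f$data * object$scales["ref"]
  if (!is.null(object$bias)) {
    b <- evaluate_bias(object$bias, space_grid(object$space))
    f$data <- f$data * array(b, dim(f$data))
  }
  g <- object$images$mov_scalar
  g$data <- g$data * object$scales["mov"]
  warped <- resample_image(g, object$warp)
  fr <- resample_image(f, warp_field(object$warp$grid))   # f on warp space
  image3d(fr$data - warped$data, object$space$voxel_size, object$space$affine)
}

#' Plot the cost trace of a fit
#'
#' @param x an `mmreg_fit`.
#' @param ... passed to [plot()].
#' @export
plot.mmreg_fit <- function(x, ...) {
  tr <- x$trace
  idx <- seq_len(nrow(tr))
  graphics::plot(idx, tr$total, type = "b", pch = 16,
                 col = tr$level, xlab = "Gauss-Newton step",
                 ylab = "total cost", ...)
  graphics::legend("topright", legend = paste("level", unique(tr$level)),
                   col = unique(tr$level), pch = 16, bty = "n")
  invisible(x)
}
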