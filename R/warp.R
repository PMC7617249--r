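## The transformation model: a displacement field parametrised by uniform
## cubic B-splines on a knot grid covering the warp space, one independent
## coefficient set per displacement direction.  The B-spline design matrix is
## never materialised; displacements and their spatial derivatives are
## evaluated by separable convolution with the 4 active splines per axis.

#' Knot grid covering a warp space
#'
#' The stored splines are exactly those whose support overlaps the domain:
#' for a cubic spline (support radius two knot spacings) this places the
#' first and last knot one knot spacing outside the domain on every axis,
#' so that every interior point lies in the support of exactly four splines
#' per axis.
#'
#' @param space a [warp_space()].
#' @param spacing_mm knot spacing in mm (length 1 or 3).
#' @return an object of class `knot_grid` with per-axis spline counts,
#'   spacing in voxels, and the total number of splines `M`.
#' @export
knot_grid <- function(space, spacing_mm) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  stopifnot(all(spacing_mm > 0))
  h <- spacing_mm / space$voxel_size              # knot spacing in voxels
  ext <- space$shape - 1                          # domain is [0, n-1] voxels
  k1 <- ceiling(ext / h + 2) - 1                  # last knot index (k0 = -1)
  counts <- as.integer(k1 + 2L)
  structure(list(space = space, spacing_mm = spacing_mm, spacing_vox = h,
                 counts = counts, M = prod(counts),
                 origin_mm = as.numeric(xform_pts(space$affine,
                                                  matrix(-h, 1, 3)))),
            class = "knot_grid")
}

#' @export
print.knot_grid <- function(x, ...) {
  cat("<knot_grid> ", paste(x$counts, collapse = " x "), " splines (M = ",
      x$M, "), spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' B-spline displacement field
#'
#' @param grid a [knot_grid()].
#' @param coeffs `3 x M` matrix of displacement coefficients in mm (rows are
#'   the x, y, z world directions); defaults to the identity warp (all zero).
#' @return an object of class `warp_field`.
#' @export
warp_field <- function(grid, coeffs = NULL) {
  stopifnot(inherits(grid, "knot_grid"))
  if (is.null(coeffs)) coeffs <- matrix(0, 3, grid$M)
  stopifnot(is.matrix(coeffs), nrow(coeffs) == 3, ncol(coeffs) == grid$M,
            all(is.finite(coeffs)))
  structure(list(grid = grid, coeffs = coeffs), class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  cat("<warp_field> ", paste(x$grid$counts, collapse = " x "),
      " splines per direction, knot spacing ",
      paste(signif(x$grid$spacing_mm, 4), collapse = " x "), " mm, max |d| = ",
      signif(max(abs(x$coeffs)), 4), " mm (coefficient)\n", sep = "")
  invisible(x)
}

## Per-axis basis bookkeeping for points given as 0-based warp-space voxel
## coordinates.  Storage position: t = x / h + 1 (first stored knot sits at
## voxel coordinate -h).
warp_axis_weights <- function(grid, vox, deriv = c(0L, 0L, 0L)) {
  lapply(1:3, function(a)
    .bs_axis(vox[, a] / grid$spacing_vox[a] + 1, grid$counts[a],
             deriv = deriv[a]))
}

## Evaluate one direction's coefficient array with given per-axis weights.
.warp_eval_dir <- function(warp, d, axw) {
  .bs_eval3(array(warp$coeffs[d, ], warp$grid$counts), axw)
}

#' Displacement of a warp at given points
#'
#' @param warp a [warp_field()].
#' @param vox `N x 3` matrix of 0-based warp-space voxel coordinates.
#' @return `N x 3` matrix of displacements in mm (world frame).
#' @export
warp_displacement <- function(warp, vox) {
  axw <- warp_axis_weights(warp$grid, vox)
  cbind(.warp_eval_dir(warp, 1, axw),
        .warp_eval_dir(warp, 2, axw),
        .warp_eval_dir(warp, 3, axw))
}

#' Apply a warp to warp-space coordinates
#'
#' Maps 0-based warp-space voxel coordinates to world coordinates of the
#' moving image: `phi(x) = A x + d(x)` where `A` is the warp-space affine
#' and `d` the B-spline displacement in mm.
#'
#' @inheritParams warp_displacement
#' @return `N x 3` matrix of world coordinates (mm) with attribute `inside`
#'   flagging points that lie within the warp-space domain.
#' @export
apply_warp <- function(warp, vox) {
  sp <- warp$grid$space
  out <- xform_pts(sp$affine, vox) + warp_displacement(warp, vox)
  n <- sp$shape
  inside <- vox[, 1] >= 0 & vox[, 1] <= n[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= n[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= n[3] - 1
  attr(out, "inside") <- inside
  out
}

#' Local Jacobian of a warp
#'
#' Returns the 3x3 Jacobian of the world-coordinate mapping at each point,
#' `J = I + D d / D x_world`, using the closed-form B-spline derivatives.
#'
#' @inheritParams warp_displacement
#' @return `N x 9` matrix; each row is a 3x3 Jacobian in column-major order.
#' @export
warp_jacobian <- function(warp, vox) {
  Ainv <- solve(warp$grid$space$affine[1:3, 1:3])
  N <- nrow(vox)
  J <- matrix(0, N, 9)
  for (a in 1:3) {                      # voxel-coordinate derivative axis
    dv <- c(0L, 0L, 0L)
    dv[a] <- 1L
    axw <- warp_axis_weights(warp$grid, vox, deriv = dv)
    sc <- 1 / warp$grid$spacing_vox[a]  # chain rule: per-voxel derivative
    Dd <- cbind(.warp_eval_dir(warp, 1, axw),
                .warp_eval_dir(warp, 2, axw),
                .warp_eval_dir(warp, 3, axw)) * sc
    ## Dd[, d] = d(displacement_d)/d(vox_a); world: multiply by Ainv[a, c]
    for (cc in 1:3) {
      for (d in 1:3) {
        J[, d + 3 * (cc - 1)] <- J[, d + 3 * (cc - 1)] + Dd[, d] * Ainv[a, cc]
      }
    }
  }
  J[, 1] <- J[, 1] + 1
  J[, 5] <- J[, 5] + 1
  J[, 9] <- J[, 9] + 1
  J
}

## ---- Hessian structure ---------------------------------------------------

#' Structural sparsity pattern of B-spline Gauss-Newton Hessians
#'
#' Entry (i, j) is structurally nonzero iff splines i and j overlap in
#' spatial support (knot offset at most 3 per axis for cubic splines); all
#' nine direction blocks share the pattern.  Parameter order is
#' direction-major: column `d * M + m` for direction `d` (0..2) and spline
#' `m` (0-based, x-fastest array order).
#'
#' @param grid a [knot_grid()].
#' @return a symmetric logical sparse matrix (`Matrix::sparseMatrix`) of
#'   dimension `3M x 3M`.
#' @export
hessian_sparsity_pattern <- function(grid) {
  cnt <- grid$counts
  M <- grid$M
  off <- -3:3
  pairs_axis <- function(n) {
    i <- unlist(lapply(off, function(d) {
      lo <- max(0L, -d)
      hi <- min(n - 1L, n - 1L - d)
      if (lo > hi) integer(0) else lo:hi
    }))
    j <- unlist(lapply(off, function(d) {
      lo <- max(0L, -d)
      hi <- min(n - 1L, n - 1L - d)
      if (lo > hi) integer(0) else (lo:hi) + d
    }))
    cbind(i, j)
  }
  px <- pairs_axis(cnt[1]); py <- pairs_axis(cnt[2]); pz <- pairs_axis(cnt[3])
  nx <- nrow(px); ny <- nrow(py); nz <- nrow(pz)
  ix <- rep(px[, 1], times = ny * nz)
  jx <- rep(px[, 2], times = ny * nz)
  iy <- rep(rep(py[, 1], each = nx), times = nz)
  jy <- rep(rep(py[, 2], each = nx), times = nz)
  iz <- rep(pz[, 1], each = nx * ny)
  jz <- rep(pz[, 2], each = nx * ny)
  mi <- ix + cnt[1] * (iy + cnt[2] * iz)
  mj <- jx + cnt[1] * (jy + cnt[2] * jz)
  di <- rep(0:2, each = length(mi) * 3)
  dj <- rep(rep(0:2, each = length(mi)), times = 3)
  Matrix::sparseMatrix(i = rep(mi, 9) + di * M + 1,
                       j = rep(mj, 9) + dj * M + 1,
                       x = TRUE, dims = c(3 * M, 3 * M))
}

#' Structural sparsity of the Gauss-Newton Hessian, combinatorially
#'
#' Computes the fraction of structurally zero entries of the `3M x 3M`
#' Gauss-Newton Hessian from the pairwise support-overlap rule without
#' materialising the pattern, so it can be evaluated for grids with millions
#' of parameters.
#'
#' @param counts spline counts per axis (length 3).
#' @return list with `n_param`, `nnz` (structurally nonzero entries) and
#'   `sparsity` (fraction of zero entries).
#' @export
hessian_sparsity_fraction <- function(counts) {
  counts <- as.numeric(rep_len(counts, 3))
  stopifnot(all(counts >= 4))
  pairs_axis <- function(n) 7 * n - 12   # sum over |offset| <= 3 of (n - |offset|)
  nnz <- 9 * prod(vapply(counts, pairs_axis, numeric(1)))
  n_param <- 3 * prod(counts)
  list(n_param = n_param, nnz = nnz, sparsity = 1 - nnz / n_param^2)
}

## ---- fitting and inversion ----------------------------------------------

## Sparse B-spline design matrix (N x M) for scalar fields on a knot grid,
## evaluated at warp-space voxel coordinates.
bspline_design <- function(grid, vox, deriv = c(0L, 0L, 0L)) {
  axw <- warp_axis_weights(grid, vox, deriv = deriv)
  N <- nrow(vox)
  cnt <- grid$counts
  ii <- jj <- xx <- vector("list", 64)
  k <- 1
  for (oz in 0:3) for (oy in 0:3) for (ox in 0:3) {
    ii[[k]] <- seq_len(N)
    jj[[k]] <- (axw[[1]]$first + ox) + cnt[1] *
      ((axw[[2]]$first + oy) + cnt[2] * (axw[[3]]$first + oz)) + 1L
    xx[[k]] <- axw[[1]]$W[, ox + 1] * axw[[2]]$W[, oy + 1] * axw[[3]]$W[, oz + 1]
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(N, grid$M))
}

#' Fit warp coefficients to a sampled displacement field
#'
#' Least-squares projection of per-point displacements onto the B-spline
#' basis of a (typically finer) knot grid; used to carry the warp between
#' pyramid levels.  A tiny relative ridge keeps splines with no data in
#' their support at zero.
#'
#' @param grid target [knot_grid()].
#' @param vox `N x 3` warp-space voxel coordinates of the samples.
#' @param disp `N x 3` displacements in mm.
#' @return a [warp_field()] on `grid`.
#' @export
fit_warp_to_displacement <- function(grid, vox, disp) {
  B <- bspline_design(grid, vox)
  BtB <- Matrix::crossprod(B)
  ridge <- 1e-8 * mean(Matrix::diag(BtB)) + 1e-12
  A <- BtB + ridge * Matrix::Diagonal(grid$M)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  coeffs <- vapply(1:3, function(d)
    as.numeric(Matrix::solve(ch, Matrix::crossprod(B, disp[, d]))),
    numeric(grid$M))
  warp_field(grid, t(coeffs))
}

#' Numerically invert a warp on a set of points
#'
#' Finds, for each target world point `y`, the warp-space voxel coordinate
#' `x` with `phi(x) = y` by fixed-point iteration on the displacement
#' (adequate for the moderate, diffeomorphic warps the package produces).
#'
#' @param warp a [warp_field()].
#' @param world `N x 3` world coordinates (mm) to invert at.
#' @param tol convergence tolerance in voxels.
#' @param maxit maximum iterations.
#' @return `N x 3` matrix of 0-based warp-space voxel coordinates.
#' @export
invert_warp_at <- function(warp, world, tol = 1e-3, maxit = 50L) {
  sp <- warp$grid$space
  Ai <- solve(sp$affine)
  x <- xform_pts(Ai, world)           # start from the identity guess
  for (it in seq_len(maxit)) {
    d <- warp_displacement(warp, x)
    xn <- xform_pts(Ai, world - d)
    step <- max(abs(xn - x))
    x <- xn
    if (step < tol) break
  }
  x
}

#' Rasterise a warp as a dense displacement volume
#'
#' @param warp a [warp_field()].
#' @param space optional sampling [warp_space()] (defaults to the warp's own
#'   space).
#' @return 4D array `(nx, ny, nz, 3)` of mm displacements at voxel centres.
#' @export
warp_to_volume <- function(warp, space = NULL) {
  if (is.null(space)) space <- warp$grid$space
  vox <- vox_in_base(space, warp$grid$space)
  d <- warp_displacement(warp, vox)
  array(d, c(space$shape, 3))
}
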