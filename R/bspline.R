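## Cubic B-spline primitives.
##
## Everything in the package that is "smooth" -- the displacement field, the
## log bias field, and the interpolation of moving images -- is built from the
## same uniform cubic B-spline basis.  The basis is never materialised as a
## matrix; fields are evaluated by separable per-axis weighting of the (at
## most) 4 active splines per axis.

#' Cubic B-spline kernel and its derivatives
#'
#' Evaluates the uniform cubic B-spline \eqn{\beta^3(v)} (unit knot spacing,
#' centred at zero, support \eqn{(-2, 2)}) or one of its first two
#' derivatives.
#'
#' @param v numeric vector of positions in knot-spacing units.
#' @param deriv derivative order: 0, 1 or 2.
#' @return numeric vector of the same length as `v`.
#' @export
bspline3 <- function(v, deriv = 0L) {
  a <- abs(v)
  s <- sign(v)
  out <- numeric(length(v))
  i1 <- a < 1
  i2 <- !i1 & a < 2
  if (deriv == 0L) {
    out[i1] <- (4 - 6 * a[i1]^2 + 3 * a[i1]^3) / 6
    out[i2] <- (2 - a[i2])^3 / 6
  } else if (deriv == 1L) {
    out[i1] <- s[i1] * (-12 * a[i1] + 9 * a[i1]^2) / 6
    out[i2] <- s[i2] * (-3 * (2 - a[i2])^2) / 6
  } else if (deriv == 2L) {
    out[i1] <- (-12 + 18 * a[i1]) / 6
    out[i2] <- (2 - a[i2])
  } else {
    stop("deriv must be 0, 1 or 2")
  }
  out
}

#' Active cubic B-spline weights at a point
#'
#' For an offset `u` from the nearest knot at or below the point (in
#' knot-spacing units, so `u` in `[0, 1)`), returns the four basis values of
#' the active splines at relative knot positions -1, 0, 1, 2.  The weights
#' sum to one for any interior point (partition of unity).
#'
#' @param u numeric vector of offsets in `[0, 1)` (values up to 2 are
#'   accepted; weights of splines outside the support are zero).
#' @param deriv derivative order passed to [bspline3()].
#' @return a `length(u) x 4` matrix of weights.
#' @export
bspline_weights <- function(u, deriv = 0L) {
  W <- cbind(bspline3(u + 1, deriv), bspline3(u, deriv),
             bspline3(u - 1, deriv), bspline3(u - 2, deriv))
  dimnames(W) <- NULL
  W
}

## Per-axis active-spline bookkeeping.
## t: continuous position in knot units measured in *storage* index space
##    (storage index 0 = first stored spline along the axis).
## M: number of stored splines along the axis.
## Returns the 0-based storage index of the first of the 4 active splines and
## the N x 4 weight matrix.  The first index is clamped so all 4 indices are
## storable; the clamp only triggers where the extra spline's weight is
## exactly zero (grid margins are chosen to guarantee this for in-domain
## points).
.bs_axis <- function(t, M, deriv = 0L) {
  i <- pmin(pmax(floor(t), 1), M - 3)
  list(first = as.integer(i) - 1L, W = bspline_weights(t - i, deriv = deriv))
}

## Separable evaluation of a 3D coefficient array at scattered points.
## coef: array (Mx, My, Mz); axw: list of 3 .bs_axis() results.
.bs_eval3 <- function(coef, axw) {
  d <- dim(coef)
  out <- numeric(length(axw[[1]]$first))
  for (oz in 0:3) {
    iz <- axw[[3]]$first + oz
    wz <- axw[[3]]$W[, oz + 1]
    for (oy in 0:3) {
      iyz <- d[1] * (axw[[2]]$first + oy) + d[1] * d[2] * iz
      wyz <- axw[[2]]$W[, oy + 1] * wz
      for (ox in 0:3) {
        idx <- (axw[[1]]$first + ox) + iyz + 1L
        out <- out + axw[[1]]$W[, ox + 1] * wyz * coef[idx]
      }
    }
  }
  out
}

## Interpolating-spline prefilter (exact cubic-spline interpolation).
## Solves the banded system (c_{v-1} + 4 c_v + c_{v+1}) / 6 = y_v for each
## column, with whole-sample mirror boundaries (c_{-1} = c_1).  Direct dense
## solve: axis lengths are modest and the factorisation cost is negligible
## next to the evaluation work.
.prefilter_cols <- function(x) {
  n <- nrow(x)
  if (n == 1L) return(x)
  B <- diag(4 / 6, n)
  B[cbind(2:n, 1:(n - 1))] <- 1 / 6
  B[cbind(1:(n - 1), 2:n)] <- 1 / 6
  B[1, 2] <- 2 / 6                       # mirror: c_0 = c_2
  B[n, n - 1] <- 2 / 6                   # mirror: c_{n+1} = c_{n-1}
  solve(B, x)
}

## Apply the prefilter along every axis of a 3D array.
bspline_prefilter <- function(arr) {
  d <- dim(arr)
  ## axis 1
  arr <- array(.prefilter_cols(matrix(arr, d[1], d[2] * d[3])), d)
  ## axis 2
  a2 <- aperm(arr, c(2, 1, 3))
  a2 <- array(.prefilter_cols(matrix(a2, d[2], d[1] * d[3])), c(d[2], d[1], d[3]))
  arr <- aperm(a2, c(2, 1, 3))
  ## axis 3
  a3 <- aperm(arr, c(3, 1, 2))
  a3 <- array(.prefilter_cols(matrix(a3, d[3], d[1] * d[2])), c(d[3], d[1], d[2]))
  aperm(a3, c(2, 3, 1))
}

## Pad a 3D coefficient array by `p` planes on each side with mirror
## extension (consistent with the mirror-boundary prefilter).
.pad_mirror <- function(arr, p = 2L) {
  d <- dim(arr)
  ix <- function(n) c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  arr[ix(d[1]), , , drop = FALSE][, ix(d[2]), , drop = FALSE][, , ix(d[3]), drop = FALSE]
}

#' Prepare a 3D array for cubic-spline interpolation
#'
#' Runs the interpolating-spline prefilter and mirror-pads the coefficient
#' array so that any point inside the voxel domain can be evaluated.
#'
#' @param arr 3D numeric array of voxel values.
#' @return an object of class `spline_coef` for [spline_sample()].
#' @export
spline_prep <- function(arr) {
  stopifnot(length(dim(arr)) == 3)
  structure(list(coef = .pad_mirror(bspline_prefilter(arr), 2L),
                 dim = dim(arr), pad = 2L),
            class = "spline_coef")
}

#' Sample a prefiltered volume by cubic-spline interpolation
#'
#' @param sc a `spline_coef` object from [spline_prep()].
#' @param vox `N x 3` matrix of 0-based voxel coordinates.
#' @param deriv integer vector of per-axis derivative orders `c(dx, dy, dz)`
#'   (each 0, 1 or 2).  Derivatives are per voxel unit.
#' @return list with `value` (numeric N) and `inside` (logical N, `TRUE`
#'   where the point lies within the voxel domain `[0, n-1]` on every axis).
#' @export
spline_sample <- function(sc, vox, deriv = c(0L, 0L, 0L)) {
  stopifnot(inherits(sc, "spline_coef"), ncol(vox) == 3)
  n <- sc$dim
  p <- sc$pad
  inside <- vox[, 1] >= 0 & vox[, 1] <= n[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= n[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= n[3] - 1
  vc <- pmin(pmax(vox, -0.5), matrix(rep(n - 0.5, each = nrow(vox)), ncol = 3))
  axw <- lapply(1:3, function(a)
    .bs_axis(vc[, a] + p, n[a] + 2L * p, deriv = deriv[a]))
  list(value = .bs_eval3(sc$coef, axw), inside = inside)
}

## Trilinear sampling of a 3D array at 0-based voxel coordinates.
## Out-of-domain points are clamped; `inside` reports domain membership.
## With `grad = TRUE` also returns the (piecewise-constant per cell)
## derivative with respect to each voxel coordinate.
trilinear_sample <- function(arr, vox, grad = FALSE) {
  n <- dim(arr)
  inside <- vox[, 1] >= 0 & vox[, 1] <= n[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= n[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= n[3] - 1
  vc <- pmin(pmax(vox, 0), matrix(rep(n - 1, each = nrow(vox)), ncol = 3))
  i0 <- pmin(floor(vc), matrix(rep(n - 2, each = nrow(vox)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- vc - i0
  out <- numeric(nrow(vox))
  gr <- if (grad) matrix(0, nrow(vox), 3) else NULL
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    wx <- if (ox) f[, 1] else 1 - f[, 1]
    wy <- if (oy) f[, 2] else 1 - f[, 2]
    wz <- if (oz) f[, 3] else 1 - f[, 3]
    idx <- (i0[, 1] + ox) + n[1] * ((i0[, 2] + oy) + n[2] * (i0[, 3] + oz)) + 1
    v <- arr[idx]
    out <- out + wx * wy * wz * v
    if (grad) {
      gr[, 1] <- gr[, 1] + (if (ox) 1 else -1) * wy * wz * v
      gr[, 2] <- gr[, 2] + (if (oy) 1 else -1) * wx * wz * v
      gr[, 3] <- gr[, 3] + (if (oz) 1 else -1) * wx * wy * v
    }
  }
  list(value = out, grad = gr, inside = inside)
}

## Nearest-neighbour sampling (labels).
nearest_sample <- function(arr, vox) {
  n <- dim(arr)
  i <- pmin(pmax(round(vox), 0), matrix(rep(n - 1, each = nrow(vox)), ncol = 3))
  arr[i[, 1] + n[1] * (i[, 2] + n[2] * i[, 3]) + 1]
}
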