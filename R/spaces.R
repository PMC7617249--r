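## Image containers and coordinate geometry.
##
## Conventions used throughout the package:
##   * voxel coordinates are 0-based and continuous; voxel (0,0,0) is the
##     centre of the first stored voxel;
##   * an image affine maps homogeneous 0-based voxel coordinates to world
##     coordinates in mm (NIfTI convention);
##   * displacements are stored in mm, in the world frame of the warp space.

#' Construct a 3D scalar image
#'
#' @param data 3D numeric array of intensities.
#' @param voxel_size voxel dimensions in mm (length 1 or 3).
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal affine with
#'   the given voxel size, centred on the volume origin at voxel (0,0,0).
#' @param premat optional FLIRT-format 4x4 matrix mapping this image into the
#'   warp space (see [read_affine()]).
#' @return an object of class `image3d`.
#' @export
image3d <- function(data, voxel_size = 1, affine = NULL, premat = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0), all(is.finite(data)))
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  stopifnot(is.matrix(affine), all(dim(affine) == 4),
            abs(det(affine)) > .Machine$double.eps)
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 premat = premat),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat("<image3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Construct a diffusion-tensor volume
#'
#' Tensors are stored as six unique elements per voxel in row-wise
#' upper-triangle order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), the layout produced
#' by FSL `dtifit`.
#'
#' @param data 4D numeric array with six volumes in the fourth dimension.
#' @param voxel_size,affine,premat as for [image3d()].
#' @return an object of class `tensor_volume`.
#' @export
tensor_volume <- function(data, voxel_size = 1, affine = NULL, premat = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (dim(data)[4] != 6)
    stop("tensor volumes must have exactly 6 components (Dxx, Dxy, Dxz, ",
         "Dyy, Dyz, Dzz); got ", dim(data)[4])
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  stopifnot(all(voxel_size > 0), all(is.finite(data)),
            abs(det(affine)) > .Machine$double.eps)
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 premat = premat),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat("<tensor_volume> ", paste(dim(x$data)[1:3], collapse = " x "),
      " voxels x 6 components\n", sep = "")
  invisible(x)
}

#' Define the warp estimation domain
#'
#' The warp space is the voxel grid over which the deformation is estimated
#' and over which all cost sums run.
#'
#' @param shape voxel counts per axis (length 3).
#' @param voxel_size voxel dimensions in mm (length 1 or 3).
#' @param affine 4x4 voxel-to-world matrix (default diagonal).
#' @return an object of class `warp_space`.
#' @export
warp_space <- function(shape, voxel_size = 1, affine = NULL) {
  shape <- as.integer(rep_len(shape, 3))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(shape >= 2), all(voxel_size > 0))
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  stopifnot(abs(det(affine)) > .Machine$double.eps)
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "warp_space")
}

#' @export
print.warp_space <- function(x, ...) {
  cat("<warp_space> ", paste(x$shape, collapse = " x "), " voxels, ",
      paste(signif(x$voxel_size, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Warp space matching an image grid
#'
#' @param img an [image3d()] or [tensor_volume()].
#' @return a [warp_space()] with the image's shape, voxel size and affine.
#' @export
space_of <- function(img) {
  warp_space(dim(img$data)[1:3], img$voxel_size, img$affine)
}

## Homogeneous transform of an N x 3 point matrix by a 4 x 4 matrix.
xform_pts <- function(A, pts) {
  out <- pts %*% t(A[1:3, 1:3])
  sweep(out, 2, A[1:3, 4], "+")
}

#' All voxel centres of a space
#'
#' @param space a [warp_space()].
#' @return `N x 3` matrix of 0-based voxel indices (x fastest, matching R
#'   array order).
#' @export
space_grid <- function(space) {
  n <- space$shape
  cbind(rep(seq_len(n[1]) - 1, times = n[2] * n[3]),
        rep(rep(seq_len(n[2]) - 1, each = n[1]), times = n[3]),
        rep(seq_len(n[3]) - 1, each = n[1] * n[2]))
}

## FSL's internal scaled-voxel coordinate system: x_fsl = voxel index *
## voxel size, with the x-axis flipped when the voxel-to-world affine has a
## positive determinant (radiological storage convention).
fsl_mat <- function(obj) {
  n <- if (inherits(obj, "warp_space")) obj$shape else dim(obj$data)[1:3]
  v <- obj$voxel_size
  S <- diag(c(v, 1))
  if (det(obj$affine) > 0) {
    Fx <- diag(4)
    Fx[1, 1] <- -1
    Fx[1, 4] <- n[1] - 1
    S <- S %*% Fx
  }
  S
}

#' World-coordinate mapping encoded by a FLIRT matrix
#'
#' A FLIRT matrix maps FSL scaled-voxel coordinates of a source image to FSL
#' scaled-voxel coordinates of a destination image.  This helper converts it
#' to a plain 4x4 mapping of NIfTI world (mm) coordinates.
#'
#' @param M 4x4 FLIRT matrix (source to destination).
#' @param src,dest source and destination [image3d()] / [warp_space()]
#'   objects (their grids and affines define the FSL coordinate systems).
#' @return 4x4 matrix mapping source world mm to destination world mm.
#' @export
flirt_to_world <- function(M, src, dest) {
  dest$affine %*% solve(fsl_mat(dest)) %*% M %*% fsl_mat(src) %*% solve(src$affine)
}

## 4x4 mapping from warp-space world mm to an image's voxel coordinates,
## honouring an optional FLIRT premat (image -> warp space).
world_to_imgvox <- function(img, space) {
  A <- solve(img$affine)
  if (!is.null(img$premat)) {
    W <- flirt_to_world(img$premat, img, space)  # img world -> warp world
    A <- A %*% solve(W)
  }
  A
}

## ---- smoothing and subsampling ------------------------------------------

## Separable Gaussian smoothing with kernel truncation at 4 sigma and
## row-renormalisation at the edges (no intensity loss at boundaries).
gauss_smooth <- function(arr, fwhm_mm, voxel_size) {
  if (all(fwhm_mm <= 0)) return(arr)
  fwhm_mm <- rep_len(fwhm_mm, 3)
  voxel_size <- rep_len(voxel_size, 3)
  d <- dim(arr)
  kmat <- function(n, sigma) {
    if (sigma <= 1e-6) return(NULL)
    r <- max(1L, ceiling(4 * sigma))
    off <- outer(seq_len(n), seq_len(n), "-")
    K <- exp(-off^2 / (2 * sigma^2))
    K[abs(off) > r] <- 0
    K / rowSums(K)
  }
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  K1 <- kmat(d[1], sig[1])
  if (!is.null(K1)) arr <- array(K1 %*% matrix(arr, d[1]), d)
  K2 <- kmat(d[2], sig[2])
  if (!is.null(K2)) {
    a <- aperm(arr, c(2, 1, 3))
    a <- array(K2 %*% matrix(a, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2, 1, 3))
  }
  K3 <- kmat(d[3], sig[3])
  if (!is.null(K3)) {
    a <- aperm(arr, c(3, 1, 2))
    a <- array(K3 %*% matrix(a, d[3]), c(d[3], d[1], d[2]))
    arr <- aperm(a, c(2, 3, 1))
  }
  arr
}

## Resample a space onto an isotropic-step coarser grid covering the same
## extent.  Returns the new warp_space; `step_mm` is clamped to be no finer
## than the native voxel size.
subsample_space <- function(space, step_mm) {
  step <- pmax(rep_len(step_mm, 3), space$voxel_size)
  fac <- step / space$voxel_size
  n_new <- pmax(2L, floor((space$shape - 1) / fac) + 1L)
  S <- diag(c(fac, 1))
  warp_space(n_new, space$voxel_size * fac, space$affine %*% S)
}

## 0-based voxel coordinates of `sub` voxel centres expressed in the voxel
## frame of `base` (both warp_space).
vox_in_base <- function(sub, base) {
  xform_pts(solve(base$affine) %*% sub$affine, space_grid(sub))
}
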