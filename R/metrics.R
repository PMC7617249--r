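## Evaluation metrics: label overlap (Jaccard index), surface distance
## (modified Hausdorff distance), tensor similarity (overall overlap and
## shape-weighted eigenvector similarity) and warp distortion (log-Jacobian
## range and cube-volume aspect ratio).

#' Jaccard index of two regions
#'
#' Intersection over union of two voxel regions on the same grid: 1 for
#' identical nonempty regions, 0 for disjoint ones.
#'
#' @param a,b logical arrays (or anything coercible with `> 0`) on the same
#'   grid.
#' @return scalar in `[0, 1]`, or `NA` when both regions are empty
#'   (undefined).
#' @export
jaccard <- function(a, b) {
  a <- as.logical(a > 0)
  b <- as.logical(b > 0)
  stopifnot(length(a) == length(b))
  un <- sum(a | b)
  if (un == 0) return(NA_real_)
  sum(a & b) / un
}

## Surface voxels of a region: region voxels with at least one
## face-adjacent (6-connectivity) background neighbour; volume boundaries
## count as background.
.surface_voxels <- function(a) {
  stopifnot(length(dim(a)) == 3)
  a <- a > 0
  n <- dim(a)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, n)
    src <- dst <- lapply(n, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):n[ax]; src[[ax]] <- 1:(n[ax] - by) }
    else { dst[[ax]] <- 1:(n[ax] + by); src[[ax]] <- (1 - by):n[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- a
  for (ax in 1:3) for (by in c(-1, 1))
    interior <- interior & shift(a, ax, by)
  which(a & !interior, arr.ind = TRUE) - 1L
}

#' Modified Hausdorff distance between two regions
#'
#' The maximum of the two average directed distances between the region
#' surfaces.  Surfaces are the voxels with a face-adjacent background
#' neighbour; distances are Euclidean between voxel centres, scaled by the
#' voxel size.
#'
#' @param a,b nonempty logical arrays on the same grid.
#' @param voxel_size voxel dimensions (mm per axis; default 1 gives voxel
#'   units).
#' @return scalar distance; 0 iff the surfaces coincide.
#' @export
mhd <- function(a, b, voxel_size = 1) {
  sa <- .surface_voxels(a)
  sb <- .surface_voxels(b)
  if (nrow(sa) == 0 || nrow(sb) == 0)
    stop("modified Hausdorff distance requires two nonempty regions")
  voxel_size <- rep_len(voxel_size, 3)
  sa <- sweep(sa, 2, voxel_size, "*")
  sb <- sweep(sb, 2, voxel_size, "*")
  dmin <- function(p, q) {
    ## chunked nearest-neighbour distances from each row of p to set q
    out <- numeric(nrow(p))
    qs <- rowSums(q^2)
    step <- max(1L, floor(2e7 / nrow(q)))
    for (s in seq(1, nrow(p), by = step)) {
      e <- min(s + step - 1, nrow(p))
      pp <- p[s:e, , drop = FALSE]
      d2 <- outer(rowSums(pp^2), qs, "+") - 2 * pp %*% t(q)
      out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
    out
  }
  max(mean(dmin(sa, sb)), mean(dmin(sb, sa)))
}

#' Pairwise label overlap metrics
#'
#' Jaccard index and modified Hausdorff distance for every label present in
#' either parcellation.
#'
#' @param la,lb integer label arrays ([image3d()] or plain arrays) on the
#'   same grid; 0 is background.
#' @param voxel_size voxel dimensions for the distances.
#' @return data frame with columns `label`, `jaccard`, `mhd` (`NA` where a
#'   region is empty in one volume).
#' @export
label_overlap <- function(la, lb, voxel_size = 1) {
  if (inherits(la, "image3d")) la <- la$data
  if (inherits(lb, "image3d")) lb <- lb$data
  labs <- sort(setdiff(unique(c(la, lb)), 0))
  out <- lapply(labs, function(l) {
    A <- la == l
    B <- lb == l
    ji <- jaccard(A, B)
    md <- if (sum(A) > 0 && sum(B) > 0) mhd(A, B, voxel_size) else NA_real_
    data.frame(label = l, jaccard = ji, mhd = md)
  })
  do.call(rbind, out)
}

## Westin linear / planar shape coefficients from sorted eigenvalues.
.westin_cl <- function(L) (L[, 1] - L[, 2]) / pmax(rowSums(L), 1e-300)
.westin_cp <- function(L) 2 * (L[, 2] - L[, 3]) / pmax(rowSums(L), 1e-300)

#' Tensor similarity metrics between a reference and a moving field
#'
#' Computes per voxel the overall tensor overlap
#' \deqn{OVL = \frac{\sum_i \lambda_i^r \lambda_i^m \langle v_i^r, v_i^m\rangle^2}
#'                  {\sum_i \lambda_i^r \lambda_i^m}}
#' and the shape-weighted eigenvector similarities `CLV1 = CL |<V1r, V1m>|`
#' and `CPV3 = CP |<V3r, V3m>|`, where the linear and planar shape
#' coefficients CL and CP are computed from the reference field only.
#'
#' @param ref,mov [tensor_volume()] objects on the same grid.
#' @param mask optional array or [image3d()]; positive voxels are included.
#' @return list with per-voxel `maps` (OVL, CL, CLV1, CP, CPV3 arrays),
#'   masked `means`, and `n_excluded` (zero-trace tensors inside the mask).
#' @export
dti_similarity <- function(ref, mov, mask = NULL) {
  stopifnot(all(dim(ref$data)[1:3] == dim(mov$data)[1:3]))
  n <- dim(ref$data)[1:3]
  Dr <- matrix(ref$data, ncol = 6)
  Dm <- matrix(mov$data, ncol = 6)
  keep <- rep(TRUE, nrow(Dr))
  if (!is.null(mask)) {
    if (inherits(mask, "image3d")) mask <- mask$data
    keep <- as.numeric(mask) > 0
  }
  tr_r <- rowSums(Dr[, c(1, 4, 6), drop = FALSE])
  tr_m <- rowSums(Dm[, c(1, 4, 6), drop = FALSE])
  nz <- tr_r != 0 & tr_m != 0
  n_excl <- sum(keep & !nz)
  sel <- keep & nz
  er <- cpp_tensor_eigen(Dr[sel, , drop = FALSE])
  em <- cpp_tensor_eigen(Dm[sel, , drop = FALSE])
  dot2 <- function(k) {
    (er$V[, 1 + 3 * (k - 1)] * em$V[, 1 + 3 * (k - 1)] +
       er$V[, 2 + 3 * (k - 1)] * em$V[, 2 + 3 * (k - 1)] +
       er$V[, 3 + 3 * (k - 1)] * em$V[, 3 + 3 * (k - 1)])
  }
  num <- den <- 0
  for (k in 1:3) {
    lp <- er$L[, k] * em$L[, k]
    num <- num + lp * dot2(k)^2
    den <- den + lp
  }
  ovl <- num / pmax(den, 1e-300)
  cl <- .westin_cl(er$L)
  cp <- .westin_cp(er$L)
  clv1 <- cl * abs(dot2(1))
  cpv3 <- cp * abs(dot2(3))
  mk <- function(v) {
    a <- array(NA_real_, n)
    a[sel] <- v
    a
  }
  list(maps = list(OVL = mk(ovl), CL = mk(cl), CLV1 = mk(clv1),
                   CP = mk(cp), CPV3 = mk(cpv3)),
       means = c(OVL = mean(ovl), CLV1 = mean(clv1), CPV3 = mean(cpv3)),
       n_excluded = n_excl)
}

#' Cube-volume aspect ratio of local Jacobians
#'
#' \deqn{CVAR = \left(\frac{s_{max}^3}{s_1 s_2 s_3}\right)^{1/3}}
#' the cube root of the ratio of the volume of the smallest regular cube
#' enclosing the locally deformed voxel to that cuboid's own volume: a pure
#' shape-distortion measure, always at least 1, and exactly 1 when the
#' local transformation is a scaled rotation.
#'
#' @param J `N x 9` matrix of row-wise Jacobians (or a single 3x3 matrix).
#' @return numeric vector of CVAR values.
#' @export
cvar <- function(J) {
  if (is.matrix(J) && all(dim(J) == c(3, 3))) J <- matrix(as.numeric(J), 1, 9)
  s <- cpp_singular_values(J)
  (s[, 1]^3 / (s[, 1] * s[, 2] * s[, 3]))^(1 / 3)
}

#' Distortion metrics of a warp
#'
#' Volumetric distortion as the 5th-95th percentile range of the
#' log-Jacobian determinant, and shape distortion as the mean cube-volume
#' aspect ratio, over a mask.
#'
#' @param warp a [warp_field()].
#' @param space optional sampling [warp_space()].
#' @param mask optional array or [image3d()] over the sampling grid.
#' @return list with `logj_range`, `mean_cvar` and the per-voxel values.
#' @export
distortion <- function(warp, space = NULL, mask = NULL) {
  base <- warp$grid$space
  if (is.null(space)) space <- base
  vox <- vox_in_base(space, base)
  J <- warp_jacobian(warp, vox)
  keep <- rep(TRUE, nrow(vox))
  if (!is.null(mask)) {
    if (inherits(mask, "image3d")) mask <- mask$data
    keep <- as.numeric(mask) > 0
  }
  dets <- .det3(J[keep, , drop = FALSE])
  if (any(dets <= 0))
    stop("non-positive Jacobian determinant inside the mask")
  lj <- log(dets)
  cv <- cvar(J[keep, , drop = FALSE])
  q <- stats::quantile(lj, c(0.05, 0.95), names = FALSE)
  list(logj_range = q[2] - q[1], mean_cvar = mean(cv),
       logj = lj, cvar = cv)
}
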